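# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain loops,
# plain sort(), textbook formulas.

# exhaustive nearest-neighbour simplex forecast (no shared code with
# .simplex_predict): embed by explicit indexing, distances by loops
oracle_simplex <- function(lib, target, E, l, horizon = 1) {
  span <- (E - 1) * l
  embed_times <- function(x) (span + 1):length(x)
  vec_at <- function(x, t) x[t - (0:(E - 1)) * l]
  lib_t <- embed_times(lib)
  lib_t <- lib_t[lib_t + horizon <= length(lib)]
  tgt_t <- embed_times(target)
  tgt_t <- tgt_t[tgt_t + horizon <= length(target)]
  preds <- numeric(length(tgt_t))
  for (i in seq_along(tgt_t)) {
    q <- vec_at(target, tgt_t[i])
    dists <- vapply(lib_t, function(t) sqrt(sum((vec_at(lib, t) - q)^2)),
                    numeric(1))
    ord <- sort.int(dists, index.return = TRUE)$ix[seq_len(E + 1)]
    d <- dists[ord]
    futures <- lib[lib_t[ord] + horizon]
    if (d[1] == 0) {
      preds[i] <- mean(futures[d == 0])
    } else {
      w <- exp(-d / d[1])
      preds[i] <- sum(w * futures) / sum(w)
    }
  }
  list(predictions = preds, observed = target[tgt_t + horizon])
}

# exhaustive concordance-pair AUC with half credit for ties
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# histogram mutual information, written independently (table() based)
oracle_mi <- function(x, y) {
  nb <- max(2, ceiling(sqrt(length(x) / 5)))
  fx <- cut(x, nb, include.lowest = TRUE)
  fy <- cut(y, nb, include.lowest = TRUE)
  j <- table(fx, fy) / length(x)
  mi <- 0
  for (a in seq_len(nrow(j))) for (b in seq_len(ncol(j))) {
    if (j[a, b] > 0) {
      mi <- mi + j[a, b] * log(j[a, b] / (sum(j[a, ]) * sum(j[, b])))
    }
  }
  mi
}

# random DAG over k nodes: each ordered pair (i < j after a random
# permutation) gets an edge with probability p
random_dag_edges <- function(k, p = 0.4) {
  nodes <- paste0("V", seq_len(k))
  perm <- sample(nodes)
  src <- character(); dst <- character()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::runif(1) < p) {
      src <- c(src, perm[i]); dst <- c(dst, perm[j])
    }
  }
  tibble::tibble(source = src, target = dst)
}

# build a bayes_net by hand from a DAG and random (or given) CPDs
make_bayes_net <- function(edges, cards, target, cpds = NULL) {
  nodes <- sort(names(cards))
  if (is.null(cpds)) {
    cpds <- lapply(stats::setNames(nodes, nodes), function(v) {
      parents <- sort(edges$source[edges$target == v])
      dims <- c(cards[[v]], unlist(cards[parents], use.names = FALSE))
      dn <- c(list(as.character(0:(cards[[v]] - 1))),
              lapply(parents, function(p) as.character(0:(cards[[p]] - 1))))
      names(dn) <- c(v, parents)
      raw <- array(stats::runif(prod(dims), 0.05, 1), dim = dims,
                   dimnames = dn)
      if (length(dims) == 1) raw / sum(raw)
      else sweep(raw, seq_along(dims)[-1],
                 apply(raw, seq_along(dims)[-1], sum), "/")
    })
  }
  structure(list(nodes = nodes, edges = edges,
                 cardinalities = unlist(cards)[nodes],
                 cpds = cpds, target = target,
                 train = NULL, test = NULL),
            class = "bayes_net")
}

# ancestral sampling from a bayes_net (used for CPD-recovery tests)
sample_bayes_net <- function(bn, n) {
  # topological order by repeatedly taking nodes whose parents are placed
  placed <- character()
  remaining <- bn$nodes
  while (length(remaining) > 0) {
    for (v in remaining) {
      parents <- setdiff(names(dimnames(bn$cpds[[v]])), v)
      if (all(parents %in% placed)) {
        placed <- c(placed, v)
        remaining <- setdiff(remaining, v)
        break
      }
    }
  }
  out <- matrix(NA_integer_, nrow = n, ncol = length(bn$nodes),
                dimnames = list(NULL, placed))
  for (v in placed) {
    tab <- bn$cpds[[v]]
    parents <- setdiff(names(dimnames(tab)), v)
    for (r in seq_len(n)) {
      idx <- matrix(c("0", as.character(out[r, parents])), nrow = 1)
      probs <- vapply(0:(bn$cardinalities[[v]] - 1), function(code) {
        idx[1] <- as.character(code)
        tab[idx]
      }, numeric(1))
      out[r, v] <- sample(0:(bn$cardinalities[[v]] - 1), 1, prob = probs)
    }
  }
  tibble::as_tibble(as.data.frame(out))[bn$nodes]
}

four_species_direct <- c("Y1->Y2", "Y2->Y3", "Y3->Y4")

edge_labels <- function(network) {
  paste0(network$source, "->", network$target)
}

# standard lake-like fixture used across BN/pipeline tests
lake_fixture_edges <- function() {
  tibble::tibble(
    source = c("temperature", "temperature", "ammonium", "phosphate",
               "oxygen"),
    target = c("oxygen", "cyano", "cyano", "cyano", "ammonium"),
    lag_steps = c(1L, 6L, 2L, 2L, 1L),
    strength = c(0.9, 0.6, 0.5, 0.5, 0.7)
  )
}

lake_fixture <- function(n = 900, seed = 5, noise_sd = 0.25) {
  simulate_lake_like(
    n, lake_fixture_edges(),
    variables = c("temperature", "oxygen", "ammonium", "phosphate", "cyano"),
    noise_sd = noise_sd, seed = seed)
}

# the lake fixture's ground-truth DAG as a causal_dag with CCM-style columns
lake_fixture_dag <- function() {
  e <- lake_fixture_edges()
  e$lag_steps <- -e$lag_steps
  e$mean_skill <- e$strength
  e$n_converged <- 20L
  e$significant <- TRUE
  e$provenance <- "ccm"
  net <- ccmbn:::new_causal_network(e, "cyano")
  dag <- to_dag(net, "cyano")
  dag
}
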