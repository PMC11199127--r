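# per-variable shift (in rows) aligning each cause with its effect: the
# target shifts 0; a parent of the target shifts by the |lag| of that edge;
# any other variable follows its maximum-skill out-edge and accumulates the
# lags along the path to the target.
compute_shifts <- function(dag) {
  target <- attr(dag, "target")
  edges <- tibble::as_tibble(dag)
  nodes <- unique(c(edges$source, edges$target, target))
  shift <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  shift[target] <- 0
  lag_of <- function(a, b) {
    v <- edges$lag_steps[edges$source == a & edges$target == b]
    if (length(v) == 0 || is.na(v[1])) 0L else abs(v[1])
  }
  resolve <- function(v, seen = character()) {
    if (!is.na(shift[[v]])) return(shift[[v]])
    if (v %in% seen) stop("cycle while resolving shifts", call. = FALSE)
    out_e <- edges[edges$source == v, , drop = FALSE]
    if (nrow(out_e) == 0) { shift[v] <<- 0; return(0) }
    if (target %in% out_e$target) {
      shift[v] <<- lag_of(v, target)
    } else {
      sk <- out_e$mean_skill
      sk[is.na(sk)] <- -Inf
      best <- out_e[order(-sk, out_e$target), ][1, ]
      shift[v] <<- lag_of(v, best$target) +
        resolve(best$target, c(seen, v))
    }
    shift[[v]]
  }
  for (v in nodes) resolve(v)
  shift
}

#' Align a categorized table with the causal lags of a DAG
#'
#' Each non-target variable is advanced by its cumulative lag toward the
#' target (see the shift rule in the details of [fit_cpds()]), so that a
#' cause's value at `t - |lag|` sits in the same row as its effect at `t`.
#' The leading rows without full coverage are dropped.
#'
#' @param table A `discrete_table` (from [categorize()]) or any tibble of
#'   integer codes plus a time column.
#' @param dag A `causal_dag` whose edges carry `lag_steps`.
#' @param time_col Name of the time column; auto-detected.
#' @return An `aligned_table`: tibble of codes with
#'   `nrow(table) - max(shift)` rows; attribute `shifts` records the applied
#'   per-variable shift, and `cutoffs`/`target` are carried over.
#' @export
shift_align <- function(table, dag, time_col = NULL) {
  s <- split_series(table, time_col)
  shifts <- compute_shifts(dag)
  n <- nrow(table)
  maxs <- max(c(0, shifts[names(shifts) %in% s$vars]))
  if (maxs >= n) stop("shift exceeds table length", call. = FALSE)
  rows <- (maxs + 1L):n
  out <- purrr::map_dfc(stats::setNames(s$vars, s$vars), function(v) {
    sh <- if (v %in% names(shifts)) shifts[[v]] else 0
    s$values[[v]][rows - sh]
  })
  res <- dplyr::bind_cols(tibble::tibble(!!s$time_col := s$time[rows]), out)
  attr(res, "shifts") <- shifts
  attr(res, "cutoffs") <- attr(table, "cutoffs")
  attr(res, "target") <- attr(table, "target")
  class(res) <- c("aligned_table", class(res))
  res
}

#' Count cases per variable state
#'
#' Over-fitting guard for discrete Bayesian networks: every state of every
#' variable should rest on more than `min_cases` observations.
#'
#' @param aligned A table of category codes (time column ignored).
#' @param min_cases Strict lower bound (default 20).
#' @param time_col Name of the time column; auto-detected.
#' @return Tibble with columns `variable`, `state`, `count`, `pass`
#'   (`count > min_cases`); attribute `pass` is the overall verdict.
#' @export
check_state_support <- function(aligned, min_cases = 20, time_col = NULL) {
  s <- split_series(aligned, time_col)
  rows <- purrr::map_dfr(stats::setNames(s$vars, s$vars), function(v) {
    x <- s$values[[v]]
    if (length(x) == 0 || all(is.na(x))) {
      return(tibble::tibble(state = NA_integer_, count = 0L))
    }
    tb <- table(factor(x, levels = 0:max(x)))
    tibble::tibble(state = as.integer(names(tb)), count = as.integer(tb))
  }, .id = "variable")
  rows$pass <- rows$count > min_cases
  attr(rows, "pass") <- all(rows$pass)
  rows
}

#' Fit conditional probability tables on a lag-aligned table
#'
#' Maximum-likelihood CPDs with add-`alpha` smoothing (default add-1), fit on
#' the chronological first `split` fraction of the rows; the remainder is
#' retained for evaluation. Smoothing guarantees proper distributions on
#' parent configurations never seen in training (they become uniform).
#'
#' @param dag A `causal_dag` (edges define each node's parents).
#' @param aligned An `aligned_table` (or any code table); must contain every
#'   DAG node.
#' @param split Chronological training fraction (default 0.75).
#' @param alpha Additive smoothing count (default 1).
#' @param min_cases State-support threshold checked before fitting
#'   (default 20); failure is a warning, not an error, so small synthetic
#'   fixtures remain usable.
#' @param time_col Name of the time column; auto-detected.
#' @return A `bayes_net`: list with `nodes`, `edges`, `cardinalities`,
#'   `cpds` (per node, an array `P(node | parents)` whose first dimension is
#'   the node), `target`, `train` and `test` row tables.
#' @export
fit_cpds <- function(dag, aligned, split = 0.75, alpha = 1, min_cases = 20,
                     time_col = NULL) {
  s <- split_series(aligned, time_col)
  edges <- tibble::as_tibble(dag)
  target <- attr(dag, "target")
  nodes <- sort(unique(c(edges$source, edges$target, target)))
  missing <- setdiff(nodes, s$vars)
  if (length(missing) > 0) {
    stop("aligned table lacks variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  support <- check_state_support(aligned, min_cases, time_col)
  if (!attr(support, "pass")) {
    warning("some variable states have <= ", min_cases,
            " cases; CPDs may over-fit", call. = FALSE)
  }
  n <- nrow(aligned)
  n_train <- floor(split * n)
  train <- s$values[seq_len(n_train), nodes, drop = FALSE]
  test_rows <- if (n_train < n) (n_train + 1L):n else integer(0)
  test <- s$values[test_rows, nodes, drop = FALSE]
  cards <- vapply(nodes, function(v) max(s$values[[v]]) + 1L, integer(1))
  cpds <- lapply(stats::setNames(nodes, nodes), function(v) {
    parents <- sort(edges$source[edges$target == v])
    dims <- c(cards[[v]], cards[parents])
    dn <- c(list(as.character(0:(cards[[v]] - 1L))),
            lapply(parents, function(p) as.character(0:(cards[[p]] - 1L))))
    names(dn) <- c(v, parents)
    counts <- array(alpha, dim = dims, dimnames = dn)
    idx <- as.matrix(train[, c(v, parents), drop = FALSE]) + 1L
    for (r in seq_len(nrow(idx))) {
      pos <- matrix(idx[r, ], nrow = 1)
      counts[pos] <- counts[pos] + 1
    }
    if (length(dims) == 1) {
      counts / sum(counts)
    } else {
      norm <- apply(counts, seq_along(dims)[-1], sum)
      sweep(counts, seq_along(dims)[-1], norm, "/")
    }
  })
  structure(list(nodes = nodes, edges = edges, cardinalities = cards,
                 cpds = cpds, target = target, train = train, test = test,
                 support = support),
            class = "bayes_net")
}

# ---- discrete factors ------------------------------------------------------

# a factor is list(vars = character, tab = array with dimnames over vars)
factor_from_cpd <- function(tab) {
  list(vars = names(dimnames(tab)), tab = tab)
}

factor_reduce <- function(f, evidence) {
  for (v in intersect(f$vars, names(evidence))) {
    code <- as.character(evidence[[v]])
    i <- match(v, f$vars)
    idx <- rep(list(quote(expr = )), length(f$vars))
    idx[[i]] <- code
    f$tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
    keep <- setdiff(seq_along(f$vars), i)
    if (length(keep) == 0) {
      f$tab <- array(as.numeric(f$tab), dim = 1)
    } else {
      dn <- dimnames(f$tab)[keep]
      f$tab <- array(f$tab, dim = dim(f$tab)[keep], dimnames = dn)
    }
    f$vars <- f$vars[keep]
  }
  f
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0) return(list(vars = f2$vars,
                                        tab = f2$tab * as.numeric(f1$tab)))
  if (length(f2$vars) == 0) return(list(vars = f1$vars,
                                        tab = f1$tab * as.numeric(f2$tab)))
  all_vars <- union(f1$vars, f2$vars)
  expand <- function(f) {
    extra <- setdiff(all_vars, f$vars)
    tab <- f$tab
    if (length(extra) > 0) {
      # recycle over appended dimensions, then permute to canonical order
      ex_dims <- lapply(extra, function(v) {
        src <- if (v %in% f2$vars) f2 else f1
        dimnames(src$tab)[[match(v, src$vars)]]
      })
      new_dim <- c(dim(tab), vapply(ex_dims, length, integer(1)))
      dn <- c(dimnames(tab), stats::setNames(ex_dims, extra))
      tab <- array(tab, dim = new_dim, dimnames = dn)
    }
    aperm(tab, match(all_vars, names(dimnames(tab))))
  }
  list(vars = all_vars, tab = expand(f1) * expand(f2))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  keep <- setdiff(seq_along(f$vars), i)
  if (length(keep) == 0) {
    return(list(vars = character(), tab = array(sum(f$tab), dim = 1)))
  }
  tab <- apply(f$tab, keep, sum)
  dn <- dimnames(f$tab)[keep]
  tab <- array(tab, dim = vapply(dn, length, integer(1)), dimnames = dn)
  list(vars = f$vars[keep], tab = tab)
}

#' Exact posterior of a query variable by variable elimination
#'
#' @param bn A `bayes_net`.
#' @param evidence Named list/vector of observed codes (integers).
#' @param query Variable to query (default the network's target).
#' @return Named numeric vector: posterior probability per code of `query`.
#'   Contradictory (zero-probability) evidence returns a uniform
#'   distribution with a warning.
#' @export
infer <- function(bn, evidence = list(), query = NULL) {
  if (is.null(query)) query <- bn$target
  stopifnot(query %in% bn$nodes)
  evidence <- as.list(evidence)
  bad <- setdiff(names(evidence), bn$nodes)
  if (length(bad) > 0) stop("unknown evidence variables: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  for (v in names(evidence)) {
    if (evidence[[v]] < 0 || evidence[[v]] >= bn$cardinalities[[v]]) {
      stop("evidence code out of range for ", v, call. = FALSE)
    }
  }
  factors <- lapply(bn$cpds, factor_from_cpd)
  factors <- lapply(factors, factor_reduce, evidence = evidence)
  hidden <- setdiff(bn$nodes, c(query, names(evidence)))
  for (v in hidden) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    prod <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod, v)))
  }
  res <- Reduce(factor_product, factors)
  if (length(res$vars) > 1) {
    for (v in setdiff(res$vars, query)) res <- factor_marginalize(res, v)
  }
  p <- as.numeric(res$tab)
  if (length(res$vars) == 1) {
    names(p) <- dimnames(res$tab)[[1]]
  } else {
    names(p) <- as.character(0:(bn$cardinalities[[query]] - 1L))
  }
  tot <- sum(p)
  if (tot <= 0 || !is.finite(tot)) {
    warning("contradictory evidence: returning uniform distribution",
            call. = FALSE)
    k <- bn$cardinalities[[query]]
    return(stats::setNames(rep(1 / k, k), as.character(0:(k - 1L))))
  }
  p / tot
}

# brute-force joint enumeration; independent oracle for infer()
infer_enumerate <- function(bn, evidence = list(), query = NULL) {
  if (is.null(query)) query <- bn$target
  grid <- do.call(expand.grid, lapply(bn$cardinalities, function(k) 0:(k - 1)))
  for (v in names(evidence)) grid <- grid[grid[[v]] == evidence[[v]], ,
                                          drop = FALSE]
  joint <- vapply(seq_len(nrow(grid)), function(r) {
    prod(vapply(bn$nodes, function(v) {
      parents <- setdiff(names(dimnames(bn$cpds[[v]])), v)
      idx <- matrix(as.character(unlist(grid[r, c(v, parents)])), nrow = 1)
      bn$cpds[[v]][idx]
    }, numeric(1)))
  }, numeric(1))
  k <- bn$cardinalities[[query]]
  p <- vapply(0:(k - 1), function(code) sum(joint[grid[[query]] == code]),
              numeric(1))
  if (sum(p) <= 0) return(stats::setNames(rep(1 / k, k),
                                          as.character(0:(k - 1))))
  stats::setNames(p / sum(p), as.character(0:(k - 1)))
}

# rank-based AUC with half credit for ties (equals exhaustive pair counting)
auc_rank <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Evaluate a Bayesian network on its held-out test partition
#'
#' For each test row the posterior P(target = 1) given the target's parents'
#' observed codes is computed; the prediction is 1 when the probability is at
#' least `cutoff`. Reports accuracy, a rank-based AUC (ties get half
#' credit) using P(target = 1) as the score, and the confusion matrix.
#'
#' @param bn A `bayes_net`.
#' @param test Optional test table of codes; defaults to the held-out
#'   partition stored in `bn`.
#' @param cutoff Probability cutoff for the positive call (default 0.5,
#'   inclusive).
#' @return A list with `accuracy`, `auc`, `confusion` (2x2 matrix,
#'   predicted x observed), `probabilities`, `observed`.
#' @export
evaluate <- function(bn, test = NULL, cutoff = 0.5) {
  if (is.null(test)) test <- bn$test
  test <- tibble::as_tibble(test)
  target <- bn$target
  parents <- sort(bn$edges$source[bn$edges$target == target])
  probs <- vapply(seq_len(nrow(test)), function(r) {
    ev <- as.list(test[r, parents, drop = FALSE])
    infer(bn, ev, query = target)[["1"]]
  }, numeric(1))
  obs <- test[[target]]
  pred <- as.integer(probs >= cutoff)
  confusion <- table(predicted = factor(pred, levels = 0:1),
                     observed = factor(obs, levels = 0:1))
  list(accuracy = mean(pred == obs),
       auc = auc_rank(probs, obs),
       confusion = confusion,
       probabilities = probs,
       observed = obs)
}

# ---- hill-climbing structure learning --------------------------------------

# BIC family score of node v with the given parent set (larger is better)
bic_family <- function(data, v, parents, cards) {
  n <- nrow(data)
  x <- data[[v]]
  if (length(parents) == 0) {
    counts <- tabulate(x + 1L, nbins = cards[[v]])
    ll <- sum(counts[counts > 0] * log(counts[counts > 0] / n))
    return(ll - 0.5 * log(n) * (cards[[v]] - 1))
  }
  key <- do.call(paste, c(data[parents], sep = "\r"))
  tab <- table(key, factor(x, levels = 0:(cards[[v]] - 1L)))
  row_tot <- rowSums(tab)
  nz <- tab > 0
  ll <- sum(tab[nz] * log(tab[nz] / row_tot[row(tab)[nz]]))
  q <- prod(cards[parents])
  ll - 0.5 * log(n) * (cards[[v]] - 1) * q
}

#' Learn a DAG by greedy hill climbing on the BIC score
#'
#' Starting from the empty graph, repeatedly applies the single edge
#' addition, removal or reversal with the largest BIC gain until no move
#' improves the score; ties are broken lexicographically by (move, source,
#' target) so the result is deterministic. This is the conventional
#' structure-learning baseline against which the cross-mapping network is
#' compared.
#'
#' @param aligned Table of category codes (time column ignored).
#' @param max_parents Parent-set cap (default 4).
#' @param time_col Name of the time column; auto-detected.
#' @return A `causal_dag` of the learned edges (no skills or lags).
#' @export
learn_structure_hillclimb <- function(aligned, max_parents = 4,
                                      time_col = NULL) {
  s <- split_series(aligned, time_col)
  data <- s$values
  if (nrow(data) == 0) stop("empty table", call. = FALSE)
  vars <- sort(s$vars)
  cards <- vapply(stats::setNames(vars, vars),
                  function(v) max(data[[v]]) + 1L, integer(1))
  parents <- stats::setNames(rep(list(character()), length(vars)), vars)
  fam_score <- vapply(vars, function(v) bic_family(data, v, character(), cards),
                      numeric(1))
  names(fam_score) <- vars
  has_edge <- function(a, b) b %in% vars && a %in% parents[[b]]
  creates_cycle <- function(a, b, par) {
    # path b ~> a under parent sets `par`?
    frontier <- a
    seen <- character()
    while (length(frontier) > 0) {
      v <- frontier[1]; frontier <- frontier[-1]
      if (v == b) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      frontier <- c(frontier, par[[v]])
    }
    FALSE
  }
  repeat {
    best <- NULL
    for (a in vars) for (b in vars) {
      if (a == b) next
      if (!has_edge(a, b)) {
        if (length(parents[[b]]) >= max_parents) next
        if (creates_cycle(a, b, parents)) next
        new_s <- bic_family(data, b, sort(c(parents[[b]], a)), cards)
        gain <- new_s - fam_score[[b]]
        mv <- list(type = "add", a = a, b = b, gain = gain,
                   upd = stats::setNames(list(new_s), b))
      } else {
        new_s <- bic_family(data, b, setdiff(parents[[b]], a), cards)
        gain <- new_s - fam_score[[b]]
        mv <- list(type = "remove", a = a, b = b, gain = gain,
                   upd = stats::setNames(list(new_s), b))
        # also consider reversal
        if (length(parents[[a]]) < max_parents) {
          par2 <- parents
          par2[[b]] <- setdiff(par2[[b]], a)
          if (!creates_cycle(b, a, par2)) {
            s_b <- new_s
            s_a <- bic_family(data, a, sort(c(parents[[a]], b)), cards)
            gain_rev <- (s_b - fam_score[[b]]) + (s_a - fam_score[[a]])
            mv_rev <- list(type = "reverse", a = a, b = b, gain = gain_rev,
                           upd = stats::setNames(list(s_b, s_a), c(b, a)))
            if (mv_rev$gain > mv$gain + 1e-9) mv <- mv_rev
          }
        }
      }
      if (is.null(best) || mv$gain > best$gain + 1e-9) best <- mv
    }
    if (is.null(best) || best$gain <= 1e-9) break
    if (best$type == "add") {
      parents[[best$b]] <- sort(c(parents[[best$b]], best$a))
    } else if (best$type == "remove") {
      parents[[best$b]] <- setdiff(parents[[best$b]], best$a)
    } else {
      parents[[best$b]] <- setdiff(parents[[best$b]], best$a)
      parents[[best$a]] <- sort(c(parents[[best$a]], best$b))
    }
    for (v in names(best$upd)) fam_score[[v]] <- best$upd[[v]]
  }
  edges <- purrr::map_dfr(vars, function(b) {
    if (length(parents[[b]]) == 0) return(NULL)
    tibble::tibble(source = parents[[b]], target = b)
  })
  out <- new_causal_network(edges, NULL)
  class(out) <- c("causal_dag", setdiff(class(out), "causal_dag"))
  out
}

#' Serialize a fitted Bayesian network to JSON
#'
#' @param bn A `bayes_net`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bayes_net <- function(bn, path) {
  obj <- list(
    nodes = bn$nodes,
    cardinalities = as.list(bn$cardinalities),
    edges = bn$edges[, c("source", "target", "lag_steps", "provenance")],
    target = bn$target,
    # row-major flattening; parent states vary fastest in R column order,
    # so we export with the node dimension first and document the order
    cpds = lapply(bn$cpds, function(tab) {
      list(dims = dim(tab), vars = names(dimnames(tab)),
           values = as.numeric(tab))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
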