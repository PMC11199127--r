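new_causal_network <- function(edges, target = NULL) {
  cols <- c("source", "target", "mean_skill", "n_converged", "lag_steps",
            "significant", "provenance")
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(source = character(), target = character(),
                            mean_skill = numeric(), n_converged = integer(),
                            lag_steps = integer(), significant = logical(),
                            provenance = character())
  }
  for (c0 in setdiff(cols, names(edges))) {
    edges[[c0]] <- switch(c0,
      mean_skill = NA_real_, n_converged = NA_integer_,
      lag_steps = NA_integer_, significant = NA,
      provenance = "ccm", NA)
  }
  out <- tibble::as_tibble(edges[cols])
  attr(out, "focus") <- target
  class(out) <- c("causal_network", class(out))
  out
}

network_nodes <- function(network) {
  sort(unique(c(network$source, network$target, attr(network, "focus"))))
}

as_igraph_network <- function(network) {
  igraph::graph_from_data_frame(network[, c("source", "target")],
                                vertices = network_nodes(network))
}

#' Build a target-focused causal network by two CCM iterations
#'
#' Iteration 1 screens every variable against the target: sliding-window CCM
#' in both directions, keeping variables whose mean converged skill reaches
#' `skill_min` in either direction. Iteration 2 runs sliding-window CCM over
#' all ordered pairs within the screening set (target included, self-pairs
#' excluded) and retains edges with mean skill at least `skill_min` over at
#' least `min_windows` converged windows.
#'
#' With `use_windows = FALSE` each pair is tested once on the full series and
#' an edge is retained when the single cross-map curve converges with final
#' skill at least `skill_min` (the paper-style single-frame comparison; the
#' window-count filter does not apply).
#'
#' @param data Tibble with a time column plus numeric variables (conditioned:
#'   uniform grid, normalized).
#' @param target Target variable name.
#' @param E,l Embedding parameters. `NULL` (the default) selects them per
#'   variable: the lag from the first minimum of lagged mutual information
#'   ([select_lag()]) and the dimension from leave-one-out simplex skill
#'   ([select_embedding_dimension()]), computed once per variable on (up to)
#'   the first 400 samples; a pair's cross map uses the parameters of the
#'   *effect* variable, whose manifold does the predicting. Selections above
#'   20 fall back to E = 5, l = 2.
#' @param window,gap Sliding-window length and step (defaults 100 and 10).
#' @param skill_min Minimal mean skill (default 0.01).
#' @param min_windows Minimal number of converged windows (default 10).
#' @param use_windows Use the sliding-window protocol (default TRUE).
#' @param time_col Name of the time column; auto-detected.
#' @param verbose Log filter decisions with `message()` (default FALSE).
#' @return A `causal_network`: tibble of surviving directed edges with
#'   columns `source`, `target`, `mean_skill`, `n_converged`, `lag_steps`
#'   (NA until ECCM refinement), `significant` (NA until the surrogate
#'   filter) and `provenance`; attribute `counts` records the stage counts
#'   (variables screened, screening survivors, candidate pairs, surviving
#'   edges).
#' @export
build_target_network <- function(data, target, E = NULL, l = NULL,
                                 window = 100,
                                 gap = 10, skill_min = 0.01, min_windows = 10,
                                 use_windows = TRUE, time_col = NULL,
                                 verbose = FALSE) {
  s <- split_series(data, time_col)
  stopifnot(target %in% s$vars)
  vars <- s$vars
  say <- function(...) if (verbose) message(...)

  params <- lapply(stats::setNames(vars, vars), function(v) {
    if (!is.null(E) && !is.null(l)) return(c(E = E, l = l))
    x <- s$values[[v]][seq_len(min(400L, nrow(data)))]
    lv <- if (is.null(l)) select_lag(x) else l
    Ev <- if (is.null(E)) select_embedding_dimension(x, 1:10, l = lv) else E
    if (Ev > 20 || lv > 20) { Ev <- 5L; lv <- 2L }
    c(E = Ev, l = lv)
  })
  if (is.null(E) || is.null(l)) {
    say("embedding per variable: ",
        paste(vars, vapply(params, function(p)
          paste0("E=", p[["E"]], ",l=", p[["l"]]), ""),
          sep = ":", collapse = " "))
  }

  cache <- new.env(parent = emptyenv())
  pair_stat <- function(a, b) {
    key <- paste(a, b, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- pair_stat_impl(a, b)
    cache[[key]]
  }
  pair_stat_impl <- function(a, b) {
    # evidence that a drives b: cross map from b's manifold, so b's
    # embedding parameters apply
    p <- params[[b]]
    if (use_windows) {
      w <- sliding_window_ccm(s$values[[a]], s$values[[b]], window = window,
                              gap = gap, E = p[["E"]], l = p[["l"]])
      c(skill = attr(w, "mean_skill"), n_conv = attr(w, "n_converged"))
    } else {
      cv <- cross_map(s$values[[a]], s$values[[b]], E = p[["E"]], l = p[["l"]])
      c(skill = attr(cv, "final_skill"),
        n_conv = as.integer(isTRUE(attr(cv, "converged"))))
    }
  }

  others <- setdiff(vars, target)
  screened <- character()
  for (v in others) {
    st1 <- pair_stat(v, target)
    st2 <- pair_stat(target, v)
    keep <- (isTRUE(st1[["n_conv"]] >= 1) && isTRUE(st1[["skill"]] >= skill_min)) ||
            (isTRUE(st2[["n_conv"]] >= 1) && isTRUE(st2[["skill"]] >= skill_min))
    say("screen ", v, ": ", if (keep) "kept" else "dropped")
    if (keep) screened <- c(screened, v)
  }
  if (length(screened) == 0) {
    warning("no variable passed the screening step; empty network",
            call. = FALSE)
    out <- new_causal_network(tibble::tibble(), target)
    attr(out, "counts") <- list(variables = length(others),
                                screening = 0L, pairs = 0L, edges = 0L)
    return(out)
  }
  set2 <- c(screened, target)
  pairs <- expand.grid(source = set2, target = set2,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]

  min_conv <- if (use_windows) min_windows else 1L
  rows <- purrr::pmap_dfr(pairs, function(source, target) {
    st <- pair_stat(source, target)
    tibble::tibble(source = source, target = target,
                   mean_skill = st[["skill"]],
                   n_converged = as.integer(st[["n_conv"]]))
  })
  keep <- !is.na(rows$mean_skill) & rows$mean_skill >= skill_min &
    rows$n_converged >= min_conv
  if (verbose) {
    for (i in seq_len(nrow(rows))) {
      say("pair ", rows$source[i], "->", rows$target[i], ": ",
          if (keep[i]) "kept" else "dropped",
          " (skill ", signif(rows$mean_skill[i], 3),
          ", converged windows ", rows$n_converged[i], ")")
    }
  }
  out <- new_causal_network(rows[keep, , drop = FALSE], target)
  attr(out, "counts") <- list(variables = length(others),
                              screening = length(screened),
                              pairs = nrow(pairs),
                              edges = sum(keep))
  out
}

#' Refine a causal network with extended-CCM lag scans
#'
#' Each retained edge gets an ECCM profile ([eccm_scan()]); edges classified
#' as `false_interaction` or `synchrony_common_force` are dropped; under
#' enslavement only the dominant (enslaving) direction survives; surviving
#' edges carry the optimal lag as `lag_steps`.
#'
#' @param network A `causal_network`.
#' @param data The series table the network was built from.
#' @inheritParams eccm_scan
#' @param time_col Name of the time column; auto-detected.
#' @return A refined `causal_network`; attribute `eccm_dropped` counts the
#'   discarded edges.
#' @export
refine_with_eccm <- function(network, data, E = 5, l = 2, frame = 400,
                             max_library = 200, shifts = 20, split = 0.75,
                             sync_tol = 0.05, time_col = NULL) {
  if (nrow(network) == 0) return(network)
  s <- split_series(data, time_col)
  # one scan per unordered pair
  key <- purrr::map2_chr(network$source, network$target,
                         ~ paste(sort(c(.x, .y)), collapse = "|"))
  profiles <- list()
  keep <- logical(nrow(network))
  lags <- rep(NA_integer_, nrow(network))
  for (i in seq_len(nrow(network))) {
    a <- network$source[i]; b <- network$target[i]
    k <- key[i]
    if (is.null(profiles[[k]])) {
      first <- sort(c(a, b))[1]
      second <- sort(c(a, b))[2]
      profiles[[k]] <- suppressWarnings(
        eccm_scan(s$values[[first]], s$values[[second]], E = E, l = l,
                  frame = frame, max_library = max_library, shifts = shifts,
                  split = split, sync_tol = sync_tol))
    }
    prof <- profiles[[k]]
    # profile direction xy = (alphabetical first -> second)
    fwd <- a == sort(c(a, b))[1]
    cls <- attr(prof, "classification")
    edge_cls <- if (fwd) cls else chartr_direction(cls)
    keep[i] <- edge_cls %in% c("unidirectional_xy", "bidirectional",
                               "synchrony_enslaved_xy")
    lags[i] <- if (fwd) attr(prof, "opt_lag_xy") else attr(prof, "opt_lag_yx")
  }
  out <- network[keep, , drop = FALSE]
  out$lag_steps <- as.integer(pmin(lags[keep], 0L))
  out <- new_causal_network(out, attr(network, "focus"))
  attr(out, "counts") <- attr(network, "counts")
  attr(out, "eccm_dropped") <- sum(!keep)
  out
}

# swap the xy/yx suffix of a classification label
chartr_direction <- function(cls) {
  switch(cls,
         unidirectional_xy = "unidirectional_yx",
         unidirectional_yx = "unidirectional_xy",
         synchrony_enslaved_xy = "synchrony_enslaved_yx",
         synchrony_enslaved_yx = "synchrony_enslaved_xy",
         cls)
}

#' Drop edges that fail the surrogate significance test
#'
#' Runs [surrogate_significance()] per edge (surrogates applied to the
#' putative cause) and removes edges whose observed skill does not strictly
#' exceed the null quantile.
#'
#' @param network A `causal_network`.
#' @param data The series table.
#' @inheritParams surrogate_significance
#' @param time_col Name of the time column; auto-detected.
#' @return Filtered `causal_network` with `significant` and `surrogate_q`
#'   columns filled in; attribute `n_significant` records the survivors.
#' @export
apply_surrogate_filter <- function(network, data, E = 5, l = 2, n = 1000,
                                   q = 0.9, frame = 400, seed = NULL,
                                   time_col = NULL) {
  if (nrow(network) == 0) return(network)
  s <- split_series(data, time_col)
  if (!is.null(seed)) set.seed(seed)
  res <- purrr::map(seq_len(nrow(network)), function(i) {
    suppressWarnings(surrogate_significance(
      s$values[[network$source[i]]], s$values[[network$target[i]]],
      E = E, l = l, n_surrogates = n, quantile = q, frame = frame))
  })
  network$significant <- purrr::map_lgl(res, "significant")
  network$surrogate_q <- purrr::map_dbl(res, "surrogate_q")
  out <- network[network$significant, , drop = FALSE]
  out <- tibble::as_tibble(out)
  class(out) <- class(network)
  attr(out, "focus") <- attr(network, "focus")
  attr(out, "counts") <- attr(network, "counts")
  attr(out, "n_significant") <- nrow(out)
  out
}

# first directed cycle found by DFS over lexicographically sorted nodes and
# neighbours; NULL when acyclic. Deterministic by construction.
find_cycle <- function(edges) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  adj <- lapply(stats::setNames(nodes, nodes),
                function(v) sort(edges$target[edges$source == v]))
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 active 2 done
  stack <- character()
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (!is.null(result)) return()
      if (color[w] == 1L) {
        i <- match(w, stack)
        result <<- stack[i:length(stack)]
        return()
      }
      if (color[w] == 0L) visit(w)
    }
    stack <<- stack[-length(stack)]
    color[v] <<- 2L
  }
  for (v in nodes) {
    if (color[v] == 0L) visit(v)
    if (!is.null(result)) break
  }
  result
}

#' Convert a causal network to a directed acyclic graph
#'
#' Feedback loops cannot enter a Bayesian network, so cycles are broken in a
#' deterministic canonical order: while a cycle exists, if it contains the
#' target the target's out-edge within the cycle is removed (the target's
#' in-edges are never touched); otherwise the lowest-skill cycle edge
#' entering a confounder (a node with at least two out-edges) is removed,
#' ties resolved lexicographically; a cycle without a confounder loses its
#' lowest-skill edge. Finally, non-target sink nodes (no out-edges) are
#' deleted repeatedly.
#'
#' @param network A `causal_network`.
#' @param target The target variable (defaults to the network's focus).
#' @return A `causal_dag` (same tibble layout, acyclic, attribute `target`).
#' @export
to_dag <- function(network, target = NULL) {
  if (is.null(target)) target <- attr(network, "focus")
  stopifnot(!is.null(target))
  edges <- tibble::as_tibble(network)
  repeat {
    if (nrow(edges) == 0) break
    cyc <- find_cycle(edges)
    if (is.null(cyc)) break
    nxt <- c(cyc[-1], cyc[1])
    cyc_edges <- tibble::tibble(source = cyc, target = nxt)
    if (target %in% cyc) {
      drop <- cyc_edges[cyc_edges$source == target, ][1, ]
    } else {
      out_deg <- table(edges$source)
      confounders <- names(out_deg)[out_deg >= 2]
      cand <- cyc_edges[cyc_edges$target %in% confounders, , drop = FALSE]
      if (nrow(cand) == 0) cand <- cyc_edges
      sk <- purrr::map2_dbl(cand$source, cand$target, function(a, b) {
        v <- edges$mean_skill[edges$source == a & edges$target == b]
        if (length(v) == 0 || is.na(v[1])) Inf else v[1]
      })
      cand <- cand[order(sk, cand$source, cand$target), , drop = FALSE]
      drop <- cand[1, ]
    }
    edges <- edges[!(edges$source == drop$source &
                       edges$target == drop$target), , drop = FALSE]
  }
  # prune non-target sinks repeatedly
  repeat {
    nodes <- unique(c(edges$source, edges$target))
    sinks <- setdiff(nodes[!nodes %in% edges$source], target)
    if (length(sinks) == 0) break
    edges <- edges[!(edges$target %in% sinks), , drop = FALSE]
  }
  out <- new_causal_network(edges, target)
  attr(out, "counts") <- attr(network, "counts")
  class(out) <- c("causal_dag", setdiff(class(out), "causal_dag"))
  attr(out, "target") <- target
  out
}

#' Add expert-knowledge edges to a DAG
#'
#' Mechanistically established interactions absent from the data-driven
#' network (e.g. nutrient limitation of a bloom former) can be appended with
#' `provenance = "expert"`. An edge that would create a cycle is rejected;
#' duplicates are ignored.
#'
#' @param dag A `causal_dag`.
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `lag_steps` (default 0).
#' @return The extended `causal_dag`.
#' @export
add_expert_edges <- function(dag, edges) {
  edges <- tibble::as_tibble(edges)
  if (!"lag_steps" %in% names(edges)) edges$lag_steps <- 0L
  cur <- tibble::as_tibble(dag)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    dup <- any(cur$source == e$source & cur$target == e$target)
    if (dup) next
    trial <- dplyr::bind_rows(cur[, c("source", "target")],
                              e[, c("source", "target")])
    if (!is.null(find_cycle(trial))) {
      stop("expert edge ", e$source, " -> ", e$target,
           " would create a cycle", call. = FALSE)
    }
    cur <- dplyr::bind_rows(cur, tibble::tibble(
      source = e$source, target = e$target, mean_skill = NA_real_,
      n_converged = NA_integer_, lag_steps = as.integer(e$lag_steps),
      significant = NA, provenance = "expert"))
  }
  out <- new_causal_network(cur, attr(dag, "target"))
  attr(out, "counts") <- attr(dag, "counts")
  class(out) <- c("causal_dag", setdiff(class(out), "causal_dag"))
  attr(out, "target") <- attr(dag, "target")
  out
}

#' Serialize a network or DAG to JSON / DOT / adjacency CSV
#'
#' @param network A `causal_network` or `causal_dag`.
#' @param path Output file; format chosen by extension (`.json`, `.dot`,
#'   `.csv` for a binary adjacency matrix).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  ext <- tolower(tools::file_ext(path))
  edges <- tibble::as_tibble(network)
  if (ext == "json") {
    jsonlite::write_json(edges, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (ext == "dot") {
    lines <- c("digraph causal {",
               sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];", edges$source,
                       edges$target, signif(edges$mean_skill, 3)),
               "}")
    writeLines(lines, path)
  } else if (ext == "csv") {
    nodes <- network_nodes(network)
    adj <- matrix(0L, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    adj[cbind(edges$source, edges$target)] <- 1L
    utils::write.csv(adj, path)
  } else {
    stop("unsupported extension: ", ext, call. = FALSE)
  }
  invisible(path)
}
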