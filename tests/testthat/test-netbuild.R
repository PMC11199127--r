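mk_net <- function(edges, target = NULL) {
  ccmbn:::new_causal_network(tibble::as_tibble(edges), target)
}

test_that("loop truncation follows the stated cycle rules", {
  # cycle A -> B -> C -> A with target B: B's out-edge in the cycle goes
  net <- mk_net(tibble::tibble(
    source = c("A", "B", "C"), target = c("B", "C", "A"),
    mean_skill = c(0.5, 0.4, 0.3)), "B")
  dag <- to_dag(net, "B")
  expect_setequal(edge_labels(dag), c("A->B", "C->A"))
  # already-acyclic network: unchanged except sink pruning
  net2 <- mk_net(tibble::tibble(
    source = c("A", "B"), target = c("B", "C"),
    mean_skill = c(0.5, 0.4)), "B")
  dag2 <- to_dag(net2, "B")
  expect_setequal(edge_labels(dag2), "A->B")  # C was a non-target sink
  # a non-target node with only incoming edges is removed
  net3 <- mk_net(tibble::tibble(
    source = c("A", "A"), target = c("T", "D"),
    mean_skill = c(0.5, 0.4)), "T")
  expect_setequal(edge_labels(to_dag(net3, "T")), "A->T")
})

test_that("cycles without the target lose a confounder in-edge by weakest skill", {
  # cycle A -> B -> C -> A; A also drives T and D, so A is a confounder
  net <- mk_net(tibble::tibble(
    source = c("A", "B", "C", "A", "A"),
    target = c("B", "C", "A", "T", "D"),
    mean_skill = c(0.9, 0.8, 0.2, 0.5, 0.6)), "T")
  dag <- to_dag(net, "T")
  expect_false("C->A" %in% edge_labels(dag))  # weakest edge into confounder A
  expect_true("A->T" %in% edge_labels(dag))
  expect_true(igraph::is_dag(ccmbn:::as_igraph_network(dag)))
})

test_that("random cyclic networks become DAGs, idempotently, keeping target in-edges", {
  set.seed(77)
  for (i in 1:30) {
    k <- sample(4:8, 1)
    nodes <- paste0("N", seq_len(k))
    n_e <- sample(k:(2 * k), 1)
    edges <- tibble::tibble(
      source = sample(nodes, n_e, replace = TRUE),
      target = sample(nodes, n_e, replace = TRUE))
    edges <- dplyr::distinct(edges[edges$source != edges$target, ])
    if (nrow(edges) == 0) next
    edges$mean_skill <- runif(nrow(edges), 0.01, 0.9)
    target <- sample(nodes, 1)
    net <- mk_net(edges, target)
    dag <- to_dag(net, target)
    # independent acyclicity check via igraph topological sort
    g <- ccmbn:::as_igraph_network(dag)
    expect_true(igraph::is_dag(g))
    expect_length(igraph::topo_sort(g), length(igraph::V(g)))
    # idempotence
    expect_equal(edge_labels(to_dag(dag, target)), edge_labels(dag))
    # every in-edge of the target survives
    in_edges <- edges[edges$target == target, , drop = FALSE]
    if (nrow(in_edges) > 0) {
      expect_true(all(paste0(in_edges$source, "->", target) %in%
                        edge_labels(dag)))
    }
    # no non-target sinks remain
    nodes_left <- unique(c(dag$source, dag$target))
    sinks <- setdiff(nodes_left[!nodes_left %in% dag$source], target)
    expect_length(sinks, 0)
  }
})

test_that("expert edges are appended safely", {
  dag <- to_dag(mk_net(tibble::tibble(
    source = "A", target = "T", mean_skill = 0.5), "T"), "T")
  out <- add_expert_edges(dag, tibble::tibble(source = "P", target = "T"))
  expect_true("P->T" %in% edge_labels(out))
  expect_equal(out$provenance[out$source == "P"], "expert")
  expect_equal(out$lag_steps[out$source == "P"], 0L)
  # duplicates are ignored
  again <- add_expert_edges(out, tibble::tibble(source = "P", target = "T"))
  expect_equal(nrow(again), nrow(out))
  # cycle-creating edges are rejected
  expect_error(add_expert_edges(out, tibble::tibble(source = "T",
                                                    target = "A")), "cycle")
})

test_that("target network construction recovers the four-species direct chain", {
  s <- simulate_four_species(1000, seed = 1)
  net <- build_target_network(s, "Y4")
  found <- edge_labels(net)
  expect_true(all(four_species_direct %in% found))
  cnt <- attr(net, "counts")
  expect_equal(cnt$variables, 3)
  # candidate pairs bounded by k(k-1) over the screening set plus target
  expect_lte(cnt$pairs, (cnt$screening + 1) * cnt$screening)
  expect_equal(cnt$edges, nrow(net))
  # all-constant input yields an empty network with a warning
  const <- tibble::tibble(time = 1:200, a = rep(1, 200), b = rep(2, 200),
                          t = rep(3, 200))
  expect_warning(empty <- build_target_network(const, "t", E = 2, l = 1),
                 "screening")
  expect_equal(nrow(empty), 0)
})

test_that("ECCM refinement drops false interactions and keeps causal lags", {
  # empty network passes through
  empty <- mk_net(tibble::tibble(source = character(), target = character(),
                                 mean_skill = numeric()), "T")
  expect_equal(nrow(refine_with_eccm(empty, tibble::tibble(time = 1:10))), 0)
  # two variables enslaved to a common chaotic force respond instantaneously
  # with similar skill: the edge is synchrony, not causality, and is dropped
  set.seed(44)
  s <- simulate_four_species(500, seed = 9)
  z <- s$Y1
  d <- tibble::tibble(time = 1:500,
                      a = pmin(pmax(z + rnorm(500, 0, 0.01), 0), 1),
                      b = pmin(pmax(z + rnorm(500, 0, 0.01), 0), 1))
  net <- mk_net(tibble::tibble(source = "a", target = "b",
                               mean_skill = 0.2, n_converged = 12L), NULL)
  ref <- refine_with_eccm(net, d, E = 2, l = 1, frame = 400, shifts = 5)
  expect_equal(nrow(ref), 0)
  expect_equal(attr(ref, "eccm_dropped"), 1)
  # a genuine lagged dependence keeps its (non-positive) lag
  x <- as.numeric(arima.sim(list(ar = 0.8), 450))
  x <- (x - min(x)) / diff(range(x))
  y <- c(rep(x[1], 3), x[1:447])
  d2 <- tibble::tibble(time = 1:450, x = x, y = y)
  net2 <- mk_net(tibble::tibble(source = "x", target = "y",
                                mean_skill = 0.5, n_converged = 12L), NULL)
  ref2 <- refine_with_eccm(net2, d2, E = 5, l = 2, frame = 400, shifts = 10)
  expect_equal(nrow(ref2), 1)
  expect_lte(ref2$lag_steps, 0)
})

test_that("surrogate filtering keeps real edges and drops noise edges", {
  s <- simulate_four_species(700, seed = 2)
  set.seed(3)
  d <- tibble::tibble(time = 1:700, Y1 = s$Y1, Y2 = s$Y2, noise = rnorm(700))
  net <- mk_net(tibble::tibble(
    source = c("Y1", "noise"), target = c("Y2", "Y2"),
    mean_skill = c(0.5, 0.1), n_converged = c(20L, 12L)), "Y2")
  filt <- suppressWarnings(apply_surrogate_filter(net, d, E = 2, l = 1,
                                                  n = 100, q = 0.9,
                                                  seed = 10))
  expect_true("Y1->Y2" %in% edge_labels(filt))
  expect_false("noise->Y2" %in% edge_labels(filt))
  # q = 0 removes nothing (observed skill always exceeds the null minimum
  # for a coupled pair)
  filt0 <- suppressWarnings(apply_surrogate_filter(
    mk_net(tibble::tibble(source = "Y1", target = "Y2", mean_skill = 0.5,
                          n_converged = 20L), "Y2"),
    d, E = 2, l = 1, n = 100, q = 0, seed = 10))
  expect_equal(nrow(filt0), 1)
})

test_that("network serialization round-trips edges and formats", {
  net <- mk_net(tibble::tibble(source = c("A", "B"), target = c("B", "C"),
                               mean_skill = c(0.5, 0.25)), "C")
  tmp <- withr::local_tempdir()
  j <- file.path(tmp, "net.json")
  write_network(net, j)
  back <- tibble::as_tibble(jsonlite::fromJSON(j))
  expect_equal(back$source, net$source)
  expect_equal(back$mean_skill, net$mean_skill)
  d <- file.path(tmp, "net.dot")
  write_network(net, d)
  expect_true(any(grepl("\"A\" -> \"B\"", readLines(d))))
  csv <- file.path(tmp, "net.csv")
  write_network(net, csv)
  adj <- as.matrix(utils::read.csv(csv, row.names = 1))
  expect_equal(sum(adj), 2)
  expect_equal(adj["A", "B"], 1L, ignore_attr = TRUE)
})
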