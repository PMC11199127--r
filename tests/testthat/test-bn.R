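simple_dag <- function(edges, target) {
  net <- ccmbn:::new_causal_network(tibble::as_tibble(edges), target)
  class(net) <- c("causal_dag", class(net))
  attr(net, "target") <- target
  net
}

test_that("shift alignment advances causes by their lag into the target", {
  tab <- tibble::tibble(time = 1:10, A = 0:9, B = 10:19, T = 20:29)
  # all lags zero: identity
  dag0 <- simple_dag(tibble::tibble(
    source = c("A", "B"), target = c("T", "T"),
    mean_skill = c(0.5, 0.4), lag_steps = c(0L, 0L)), "T")
  al0 <- shift_align(tab, dag0)
  expect_equal(nrow(al0), 10)
  expect_equal(al0$A, tab$A)
  # single cause at lag -2: cause advanced 2 rows, 2 rows dropped
  dag1 <- simple_dag(tibble::tibble(source = "A", target = "T",
                                    mean_skill = 0.5, lag_steps = -2L), "T")
  al1 <- shift_align(tab[, c("time", "A", "T")], dag1)
  expect_equal(nrow(al1), 8)
  expect_equal(al1$T, 22:29)
  expect_equal(al1$A, 0:7)  # the cause's value from 2 rows earlier
  # two causes at lags -1 and -3: max shift of 3 rows dropped
  dag2 <- simple_dag(tibble::tibble(
    source = c("A", "B"), target = c("T", "T"),
    mean_skill = c(0.5, 0.4), lag_steps = c(-1L, -3L)), "T")
  al2 <- shift_align(tab, dag2)
  expect_equal(nrow(al2), 7)
  expect_equal(al2$A, 2:8)
  expect_equal(al2$B, 10:16)
  expect_equal(al2$T, 23:29)
  # indirect causes accumulate lags along the path to the target
  dag3 <- simple_dag(tibble::tibble(
    source = c("B", "A"), target = c("A", "T"),
    mean_skill = c(0.4, 0.5), lag_steps = c(-1L, -2L)), "T")
  al3 <- shift_align(tab, dag3)
  sh <- attr(al3, "shifts")
  expect_equal(sh[["B"]], 3)  # 1 along B->A plus 2 along A->T
  expect_equal(sh[["A"]], 2)
  dag_big <- simple_dag(tibble::tibble(source = "A", target = "T",
                                       mean_skill = 0.5,
                                       lag_steps = -12L), "T")
  expect_error(shift_align(tab, dag_big), "exceeds")
})

test_that("state-support counting uses the strict > rule", {
  tab <- tibble::tibble(time = 1:90, x = rep(0:2, 30), t = rep(0:1, 45))
  rep1 <- check_state_support(tab, 20)
  expect_true(attr(rep1, "pass"))
  tab2 <- tibble::tibble(time = 1:40, x = c(rep(0L, 20), rep(1L, 20)))
  rep2 <- check_state_support(tab2, 20)
  expect_false(attr(rep2, "pass"))  # exactly 20 cases fails
  rep3 <- check_state_support(tibble::tibble(time = integer(),
                                             x = integer()))
  expect_false(attr(rep3, "pass"))
})

test_that("CPD fitting applies add-one smoothing and chronological splits", {
  # parentless node with codes 1,1,0,0 and alpha = 1: (2+1)/(4+2) = 0.5
  tab <- tibble::tibble(time = 1:4, T = c(1L, 1L, 0L, 0L))
  dag <- simple_dag(tibble::tibble(source = character(),
                                   target = character(),
                                   mean_skill = numeric(),
                                   lag_steps = integer()), "T")
  bn <- suppressWarnings(fit_cpds(dag, tab, split = 1))
  expect_equal(unname(bn$cpds$T["1"]), 0.5)
  # unseen parent configuration yields a uniform column
  tab2 <- tibble::tibble(time = 1:20, A = rep(c(0L, 1L), 10),
                         T = rep(c(0L, 1L), 10))
  tab2$A[20] <- 2L  # state 2 only in the test partition
  dag2 <- simple_dag(tibble::tibble(source = "A", target = "T",
                                    mean_skill = 0.5, lag_steps = 0L), "T")
  bn2 <- suppressWarnings(fit_cpds(dag2, tab2, split = 0.75))
  expect_equal(unname(bn2$cpds$T[, "2"]), c(0.5, 0.5))
  expect_equal(nrow(bn2$train), 15)
  expect_equal(nrow(bn2$test), 5)
  # every CPD column sums to 1
  for (v in bn2$nodes) {
    tabv <- bn2$cpds[[v]]
    if (length(dim(tabv)) == 1) expect_equal(sum(tabv), 1)
    else expect_equal(unname(apply(tabv, 2, sum)), rep(1, ncol(tabv)))
  }
})

test_that("a deterministic parent-child CPD is recovered from samples", {
  set.seed(50)
  n <- 600
  A <- sample(0:2, n, replace = TRUE)
  tab <- tibble::tibble(time = 1:n, A = A, T = as.integer(A == 2))
  dag <- simple_dag(tibble::tibble(source = "A", target = "T",
                                   mean_skill = 0.5, lag_steps = 0L), "T")
  bn <- suppressWarnings(fit_cpds(dag, tab, split = 1))
  expect_gt(bn$cpds$T["1", "2"], 0.95)
  expect_lt(bn$cpds$T["1", "0"], 0.05)
})

test_that("exact inference matches brute-force enumeration on random networks", {
  set.seed(60)
  for (i in 1:15) {
    k <- sample(3:8, 1)
    edges <- random_dag_edges(k, 0.45)
    cards <- stats::setNames(as.list(sample(2:3, k, replace = TRUE)),
                             paste0("V", seq_len(k)))
    bn <- make_bayes_net(edges, cards, target = "V1")
    # random evidence over a random subset
    ev_vars <- sample(setdiff(bn$nodes, "V1"),
                      sample(0:(k - 1), 1))
    ev <- lapply(stats::setNames(ev_vars, ev_vars),
                 function(v) sample(0:(bn$cardinalities[[v]] - 1), 1))
    got <- infer(bn, ev)
    want <- ccmbn:::infer_enumerate(bn, ev)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("inference edge cases behave as documented", {
  # single edge A -> T with P(T=1|A=1) = 0.8
  cpds <- list(
    A = array(c(0.5, 0.5), dim = 2, dimnames = list(A = c("0", "1"))),
    T = array(c(0.9, 0.1, 0.2, 0.8), dim = c(2, 2),
              dimnames = list(T = c("0", "1"), A = c("0", "1")))
  )
  bn <- make_bayes_net(tibble::tibble(source = "A", target = "T"),
                       list(A = 2L, T = 2L), "T", cpds = cpds)
  expect_equal(unname(infer(bn, list(A = 1))[["1"]]), 0.8)
  # evidence on all parents returns the CPD row
  expect_equal(unname(infer(bn, list(A = 0))), c(0.9, 0.1))
  # no evidence: the marginal, checked against enumeration
  expect_equal(infer(bn), ccmbn:::infer_enumerate(bn), tolerance = 1e-12)
  # contradictory evidence: uniform with a warning
  cpds$A <- array(c(1, 0), dim = 2, dimnames = list(A = c("0", "1")))
  bn0 <- make_bayes_net(tibble::tibble(source = "A", target = "T"),
                        list(A = 2L, T = 2L), "T", cpds = cpds)
  expect_warning(res <- infer(bn0, list(A = 1)), "contradictory")
  expect_equal(unname(res), c(0.5, 0.5))
  expect_error(infer(bn, list(Z = 1)), "unknown evidence")
  expect_error(infer(bn, list(A = 5)), "out of range")
})

test_that("evaluation reproduces hand-counted accuracy and AUC", {
  # CPD chosen so the three test rows score 0.9, 0.2, 0.7 against truth
  # (1, 0, 0): accuracy 2/3 and AUC 1 by exhaustive pair counting
  cpds <- list(
    A = array(rep(1 / 3, 3), dim = 3, dimnames = list(A = c("0", "1", "2"))),
    T = array(c(0.1, 0.9, 0.8, 0.2, 0.3, 0.7), dim = c(2, 3),
              dimnames = list(T = c("0", "1"), A = c("0", "1", "2")))
  )
  bn <- make_bayes_net(tibble::tibble(source = "A", target = "T"),
                       list(A = 3L, T = 2L), "T", cpds = cpds)
  test_rows <- tibble::tibble(A = c(0L, 1L, 2L), T = c(1L, 0L, 0L))
  ev <- evaluate(bn, test = test_rows)
  expect_equal(ev$probabilities, c(0.9, 0.2, 0.7))
  expect_equal(ev$accuracy, 2 / 3)
  expect_equal(ev$auc, 1)
  expect_equal(ev$auc, oracle_auc(ev$probabilities, test_rows$T))
  expect_equal(as.vector(ev$confusion), c(1, 1, 0, 1))
  # perfect and constant predictors
  expect_equal(oracle_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(ccmbn:::auc_rank(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # rank AUC equals exhaustive pair counting on random vectors
  set.seed(70)
  for (i in 1:10) {
    sc <- round(runif(30), 2)  # rounding forces ties
    tr <- rbinom(30, 1, 0.5)
    if (length(unique(tr)) < 2) next
    expect_equal(ccmbn:::auc_rank(sc, tr), oracle_auc(sc, tr))
  }
})

test_that("hill climbing matches exhaustive scoring on two-node problems", {
  set.seed(80)
  n <- 400
  # independent columns: BIC prefers the empty graph
  tab_ind <- tibble::tibble(time = 1:n,
                            A = sample(0:1, n, TRUE),
                            B = sample(0:1, n, TRUE))
  fit_ind <- learn_structure_hillclimb(tab_ind)
  expect_equal(nrow(fit_ind), 0)
  # child copies parent: BIC demands one edge (direction score-equivalent)
  A <- sample(0:1, n, TRUE)
  tab_cp <- tibble::tibble(time = 1:n, A = A, B = A)
  fit_cp <- learn_structure_hillclimb(tab_cp)
  expect_equal(nrow(fit_cp), 1)
  # exhaustive two-node oracle: score(empty) vs score(A->B)
  score_empty <- ccmbn:::bic_family(tab_cp[, -1], "A", character(),
                                    c(A = 2L, B = 2L)) +
    ccmbn:::bic_family(tab_cp[, -1], "B", character(), c(A = 2L, B = 2L))
  score_edge <- ccmbn:::bic_family(tab_cp[, -1], "A", character(),
                                   c(A = 2L, B = 2L)) +
    ccmbn:::bic_family(tab_cp[, -1], "B", "A", c(A = 2L, B = 2L))
  expect_gt(score_edge, score_empty)
  score_empty_i <- ccmbn:::bic_family(tab_ind[, -1], "A", character(),
                                      c(A = 2L, B = 2L)) +
    ccmbn:::bic_family(tab_ind[, -1], "B", character(), c(A = 2L, B = 2L))
  score_edge_i <- ccmbn:::bic_family(tab_ind[, -1], "A", character(),
                                     c(A = 2L, B = 2L)) +
    ccmbn:::bic_family(tab_ind[, -1], "B", "A", c(A = 2L, B = 2L))
  expect_gt(score_empty_i, score_edge_i)
  expect_error(learn_structure_hillclimb(tibble::tibble(time = integer(),
                                                        A = integer())),
               "empty")
  # the learned graph is acyclic
  set.seed(81)
  tab3 <- tibble::tibble(time = 1:n, A = A,
                         B = as.integer(xor(A, rbinom(n, 1, 0.1))),
                         C = sample(0:2, n, TRUE))
  fit3 <- learn_structure_hillclimb(tab3)
  if (nrow(fit3) > 0) {
    expect_true(igraph::is_dag(ccmbn:::as_igraph_network(fit3)))
  }
})
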