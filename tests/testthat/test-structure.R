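test_that("pairwise mutual information matches hand computation", {
  X <- cbind(A = c(0, 0, 1, 1), B = c(0, 1, 1, 1))
  # contingency (0,0)=1 (0,1)=1 (1,1)=2; plug-in formula by hand:
  expected <- 0.25 * log(2) + 0.25 * log(2 / 3) + 0.5 * log(4 / 3)
  expect_equal(mutual_information(X)["A", "B"], expected)

  # deterministic copy of a balanced coin: MI = ln 2
  Y <- cbind(A = rep(c(0, 1), 50), B = rep(c(0, 1), 50))
  expect_equal(mutual_information(Y)["A", "B"], log(2))

  # independent fair coins: plug-in MI small and nonnegative
  set.seed(11)
  m <- 10000
  Z <- cbind(A = rbinom(m, 1, 0.5), B = rbinom(m, 1, 0.5))
  mi <- mutual_information(Z)["A", "B"]
  expect_gte(mi, 0)
  expect_lt(mi, 3 / m + 3 * sqrt(1 / m))

  # constant column: MI 0 by convention, with warning
  W <- cbind(A = c(0, 1, 0, 1), B = c(1, 1, 1, 1))
  expect_warning(miW <- mutual_information(W), "constant")
  expect_equal(miW["A", "B"], 0)

  expect_error(mutual_information(X[1, , drop = FALSE]), "2 rows")
})

test_that("MWST ordering follows the maximum-weight tree from the root", {
  mi <- rbind(c(0, 0.5, 0.1), c(0.5, 0, 0.4), c(0.1, 0.4, 0))
  ord <- mwst_ordering(mi, root = 1)
  expect_equal(ord$order, c(1, 2, 3))
  expect_equal(ord$tree, data.frame(from = c(1, 2), to = c(2, 3)))

  # singleton
  expect_equal(mwst_ordering(matrix(0, 1, 1))$order, 1L)
  expect_error(mwst_ordering(matrix(numeric(), 0, 0)), "empty")

  # all-equal weights: tie-break is deterministic and index-driven
  eq <- matrix(1, 4, 4); diag(eq) <- 0
  o1 <- mwst_ordering(eq, root = 1)
  o2 <- mwst_ordering(eq, root = 1)
  expect_identical(o1, o2)
  expect_equal(o1$tree,
               data.frame(from = c(1, 1, 1), to = c(2, 3, 4)))

  # default root = largest total weight
  mi2 <- rbind(c(0, 0.9, 0), c(0.9, 0, 0.8), c(0, 0.8, 0))
  expect_equal(mwst_ordering(mi2)$root, 2L)
})

test_that("MWST tree weight matches an independent MST solver", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 6
    mi <- matrix(runif(n * n), n)
    mi <- (mi + t(mi)) / 2; diag(mi) <- 0
    ours <- mwst_ordering(mi, root = 1)
    w_ours <- sum(mi[cbind(ours$tree$from, ours$tree$to)])
    ig <- igraph::graph_from_adjacency_matrix(max(mi) + 1 - mi,
                                              mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(ig)
    w_ig <- sum(max(mi) + 1 - igraph::E(mst)$weight)
    expect_equal(w_ours, w_ig, tolerance = 1e-12)
  }
})

test_that("K2 local score matches the factorial formula", {
  expect_equal(k2_local_score(1, integer(), cbind(N = c(1, 0, 1))),
               log(1 / 12))
  # row-order invariance
  X <- cbind(P = c(0, 0, 1, 1, 1, 0), C = c(0, 0, 1, 1, 0, 1))
  expect_equal(k2_local_score("C", "P", X),
               k2_local_score("C", "P", X[sample(6), ]))
  # a copied parent beats the empty parent set
  expect_gt(k2_local_score("C", "P", cbind(P = c(0, 0, 0, 1, 1, 1),
                                           C = c(0, 0, 0, 1, 1, 1))),
            k2_local_score("C", integer(), cbind(P = c(0, 0, 0, 1, 1, 1),
                                                 C = c(0, 0, 0, 1, 1, 1))))
  expect_error(k2_local_score(1, integer(), cbind(N = integer(0))), "empty")
})

test_that("K2 score equals the exact-rational factorial oracle", {
  set.seed(7)
  for (rep in 1:3) {
    X <- matrix(rbinom(40, 1, 0.5), nrow = 8,
                dimnames = list(NULL, paste0("v", 1:5)))
    for (node in 1:5) {
      others <- setdiff(1:5, node)
      psets <- c(list(integer()), as.list(others),
                 combn(others, 2, simplify = FALSE))
      for (ps in psets) {
        expect_equal(k2_local_score(node, ps, X),
                     k2_oracle_exact(node, ps, X), tolerance = 1e-10)
      }
    }
  }
})

test_that("AIC local score: hand value, zero-cell convention, overfit penalty", {
  expect_equal(aic_local_score(1, integer(), cbind(N = c(1, 0, 1))),
               2 * log(2 / 3) + log(1 / 3) - 1)
  # zero-count cell: 0 log 0 = 0, score finite
  X <- cbind(P = c(1, 1, 1, 1), C = c(0, 1, 0, 1))
  expect_true(is.finite(aic_local_score("C", "P", X)))
  # an independent parent lowers AIC on average (parameter cost dominates)
  set.seed(21)
  diffs <- replicate(20, {
    Z <- cbind(P = rbinom(500, 1, 0.5), C = rbinom(500, 1, 0.4))
    aic_local_score("C", "P", Z) - aic_local_score("C", integer(), Z)
  })
  expect_lt(mean(diffs), 0)
})

test_that("penalized total score composes data score and lambda2", {
  net <- make_ground_truth(bn_spec(conditions = c("A", "B"), years = 2))
  co <- cohort_fixture(net, 200, seed = 3)
  chain <- mcc_graph(net$graph$labels,
                     data.frame(from = c(1, 2), to = c(2, 3)))
  s0 <- penalized_total_score(chain, co, score_config(lam = 0))
  expect_equal(attr(s0, "data_score"), as.numeric(s0))
  s1000 <- penalized_total_score(chain, co, score_config(lam = 1000))
  l2 <- lambda2(chain, lap_config("directed_total"))
  expect_equal(as.numeric(s1000), as.numeric(s0) - 1000 * l2)

  cyc <- mcc_graph(c("x", "y"), data.frame(from = c(1, 2), to = c(2, 1)))
  expect_error(penalized_total_score(cyc, co, score_config()), "acyclic")
})

test_that("with equal data scores, smaller lambda2 wins for any lam > 0", {
  # two 4-node graphs with identical degreeless data term (no data needed:
  # compare the penalty directly through the total on a constant cohort)
  labs <- paste0("v", 1:4)
  dense <- mcc_graph(labs, data.frame(from = c(1, 1, 1, 2, 3),
                                      to = c(2, 3, 4, 3, 4)))
  sparse <- mcc_graph(labs, data.frame(from = c(1, 2, 3),
                                       to = c(2, 3, 4)))
  l2_dense <- lambda2(dense); l2_sparse <- lambda2(sparse)
  expect_lt(l2_sparse, l2_dense)
  for (lam in c(0.1, 1, 100)) {
    expect_gt(-lam * l2_sparse, -lam * l2_dense)
  }
})

test_that("eagl_learn with lam = 0 reproduces plain MWST + K2", {
  net <- make_ground_truth(bn_spec_recovery())
  co <- cohort_fixture(net, 1500, seed = 5)
  fit <- eagl_learn(co, lam = 0)
  ref <- k2_reference(eagl:::cohort_matrix(co), fit$ordering$order,
                      max_parents = 5)
  expect_equal(fit$data_score, ref$score, tolerance = 1e-8)
  ref_edges <- do.call(rbind, lapply(seq_along(ref$parents), function(i)
    if (length(ref$parents[[i]]))
      data.frame(from = ref$parents[[i]], to = i)))
  key <- function(df) sort(paste(df$from, df$to))
  expect_equal(key(fit$graph$edges), key(ref_edges))
})

test_that("learned structures are acyclic and ordering-consistent", {
  net <- make_ground_truth(bn_spec_recovery())
  co <- cohort_fixture(net, 800, seed = 9)
  for (lam in c(0, 1, 100)) {
    fit <- eagl_learn(co, lam = lam)
    expect_true(eagl:::is_dag(fit$graph))
    pos <- match(seq_len(ncol(co) - 1), fit$ordering$order)
    expect_true(all(pos[fit$graph$edges$from] < pos[fit$graph$edges$to]))
    # temporal ordering: years nondecreasing along the ordering
    yrs <- eagl:::parse_node_label(fit$graph$labels)$year
    expect_true(!is.unsorted(yrs[fit$ordering$order]))
  }
})

test_that("edge count trends downward along the canonical lambda grid", {
  # the penalty acts once the structure spans its nodes, so the standard
  # fixture is a spanning ground truth contaminated with spurious edges
  truth <- make_ground_truth(bn_spec_recovery())
  cont <- inject_spurious_edges(truth, 12, effect_cap = 0.6, seed = 101)
  co <- cohort_fixture(cont, 2000, seed = 1)
  sweep <- eagl_sweep(co, lam_grid = c(0, 10^(-2:5)))
  e <- sweep$summary$edges
  expect_true(all(diff(e) <= 2))   # non-increasing up to 2-edge slack
  expect_lt(e[length(e)], e[1])
  # lambda2 of the learned graph decays as the penalty grows
  l2 <- sweep$summary$lambda2
  expect_true(all(diff(l2) <= 1e-9))
  # lam = 0 entry matches a direct unpenalized fit
  expect_equal(e[1], eagl:::n_edges(eagl_learn(co, lam = 0)$graph))
})

test_that("penalty_reference variants and empty-pool nodes behave", {
  net <- make_ground_truth(bn_spec(conditions = c("A", "B"), years = 2))
  co <- cohort_fixture(net, 400, seed = 2)
  fit_prev <- eagl_learn(co, lam = 5,
                         config = score_config(lam = 5,
                                               penalty_reference = "previous"))
  expect_true(eagl:::is_dag(fit_prev$graph))
  # first node in the ordering has no allowed parents yet is scored fine
  expect_equal(length(fit_prev$local_scores), 4)
})
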