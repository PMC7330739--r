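# small hand-built chain A -> B used across inference tests
chain_net <- function() {
  g <- mcc_graph(c("A", "B"), data.frame(from = 1, to = 2))
  net <- fit_cpts(g, cbind(A = c(0, 1), B = c(0, 1)), pseudo_count = 0)
  net$cpts$A$table$p1 <- 0.6
  net$cpts$B$table$p1 <- c(0.2, 0.9)   # P(B=1|A=0), P(B=1|A=1)
  net
}

test_that("CPT estimation: smoothing arithmetic and degenerate rows", {
  # child copies parent; 50 rows with parent = 1 -> P(1|1) = 51/52
  X <- cbind(P_Y1 = rep(c(0, 1), each = 50), C_Y1 = rep(c(0, 1), each = 50))
  g <- mcc_graph(colnames(X), data.frame(from = 1, to = 2))
  net <- fit_cpts(g, X, pseudo_count = 1)
  expect_equal(net$cpts$C_Y1$table$p1[2], 51 / 52)
  expect_equal(net$cpts$C_Y1$table$p1[1], 1 / 52)

  # uniform random data, large m: every entry near 0.5
  set.seed(13)
  U <- matrix(rbinom(3 * 10000, 1, 0.5), ncol = 3,
              dimnames = list(NULL, c("A_Y1", "B_Y1", "B_Y2")))
  gu <- mcc_graph(colnames(U),
                  data.frame(from = c(1, 2), to = c(3, 3)))
  netu <- fit_cpts(gu, U)
  se3 <- 3 * sqrt(0.25 / (10000 / 4))   # smallest parent-config cell ~ m/4
  expect_true(all(abs(coef(netu)$p1 - 0.5) < se3))

  # pseudo_count = 0 with an unseen parent configuration -> 0.5, flagged
  Y <- cbind(P_Y1 = c(0, 0, 0), C_Y1 = c(0, 1, 0))
  gy <- mcc_graph(colnames(Y), data.frame(from = 1, to = 2))
  nety <- fit_cpts(gy, Y, pseudo_count = 0)
  expect_equal(nety$cpts$C_Y1$table$p1[2], 0.5)
  expect_true(nety$cpts$C_Y1$table$flagged[2])

  expect_error(fit_cpts(mcc_graph(c("A_Y1", "Z_Y1"),
                                  data.frame(from = 1, to = 2)),
                        cbind(A_Y1 = c(0, 1))), "lacks column")
})

test_that("joint probability follows the network decomposition", {
  # two independent fair nodes
  g2 <- mcc_graph(c("A", "B"))
  ind <- fit_cpts(g2, cbind(A = c(0, 1), B = c(0, 1)), pseudo_count = 1)
  expect_equal(joint_probability(ind, c(A = 1, B = 1)), 0.25)

  net <- chain_net()
  expect_equal(joint_probability(net, c(A = 1, B = 0)), 0.6 * 0.1)
  expect_error(joint_probability(net, c(A = 1)), "cover every node")

  # normalization on synthetic nets up to 12 nodes
  for (spec in list(bn_spec(conditions = c("A", "B"), years = 2),
                    bn_spec(conditions = c("A", "B", "C"), years = 4))) {
    netn <- make_ground_truth(spec)
    labs <- netn$graph$labels
    total <- sum(vapply(0:(2^length(labs) - 1), function(b) {
      a <- stats::setNames(as.integer(intToBits(b)[seq_along(labs)]), labs)
      joint_probability(netn, a)
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("posterior matches Bayes rule and the enumeration oracle", {
  net <- chain_net()
  expect_equal(posterior_prob(net, c(B = 1), "A"), 0.54 / 0.62)
  # query independent of evidence: marginal returned
  g2 <- mcc_graph(c("A", "B"))
  ind <- fit_cpts(g2, cbind(A = rep(c(0, 1), c(3, 7)), B = c(0, 1)[
    rep(1:2, 5)]), pseudo_count = 0)
  expect_equal(posterior_prob(ind, c(B = 1), "A"),
               ind$cpts$A$table$p1)

  for (seed in 1:20) {
    spec <- bn_spec(conditions = c("A", "B"), years = 5,
                    prevalence = runif(2, 0.2, 0.5),
                    persistence = runif(1, 0.5, 3),
                    cross_effect = runif(1, -1, 1))
    netr <- make_ground_truth(spec)
    set.seed(seed)
    labs <- netr$graph$labels
    ev_nodes <- sample(labs, 3)
    query <- sample(setdiff(labs, ev_nodes), 1)
    ev <- stats::setNames(rbinom(3, 1, 0.5), ev_nodes)
    expect_equal(posterior_prob(netr, ev, query),
                 enumeration_posterior(netr, ev, query),
                 tolerance = 1e-10, info = paste("seed", seed))
  }

  # impossible evidence is reported as such
  det <- chain_net()
  expect_error(posterior_prob(det, c(B = 1), "B"),
               "query node is in the evidence")
  det$cpts$B$table$p1 <- c(1, 1)   # B always 1
  expect_error(posterior_prob(det, c(B = 0), "A"), "impossible evidence")
})

test_that("year-ahead prediction scores behave as posteriors", {
  spec <- bn_spec(conditions = c("A", "B"), years = 2,
                  prevalence = 0.5, onset = 1e-6,
                  edges = data.frame(from = "A_Y1", to = "A_Y2",
                                     effect = 100))   # capped at the bound
  net <- make_ground_truth(spec)
  co <- sample_cohort(net, 50, seed = 5)
  s <- predict_future(net, co, "A", 2)
  expect_true(all(abs(s - co$A_Y1) < 1e-3))   # near-copy saturation

  # identical evidence gives identical scores
  co2 <- co; co2[2, -1] <- co[1, -1]
  s2 <- predict_future(net, co2, "A", 2)
  expect_equal(s2[1], s2[2])

  # all-independent net: constant scores at the target marginal
  ind <- make_ground_truth(bn_spec(conditions = c("A", "B"), years = 2,
                                   edges = data.frame(from = character(),
                                                      to = character(),
                                                      effect = numeric())))
  si <- predict_future(ind, co, "B", 2)
  expect_equal(unique(si), ind$cpts$B_Y2$table$p1)

  expect_error(predict_future(net, co, "A", 1), "year must be >= 2")
})

test_that("AUC is the Mann-Whitney statistic with tie half-credit", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both outcome classes")

  # invariant to strictly monotone transforms
  set.seed(3)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(s, y), roc_auc(qlogis(s), y))
  expect_equal(roc_auc(s, y), roc_auc(s^3, y))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  s <- round(runif(80), 2)   # rounded scores force ties
  y <- rbinom(80, 1, 0.4)
  r <- suppressMessages(pROC::roc(y, s, levels = c(0, 1), direction = "<"))
  expect_equal(roc_auc(s, y), as.numeric(pROC::auc(r)), tolerance = 1e-12)
})

test_that("cross-validation is seed-deterministic and honest under the null", {
  net <- make_ground_truth(bn_spec_recovery())
  co <- cohort_fixture(net, 1200, seed = 44)
  pipe <- function(train) fit_cpts(net$graph, train)
  ev1 <- cross_validate(co, pipe, k = 4, seed = 9, years = 2)
  ev2 <- cross_validate(co, pipe, k = 4, seed = 9, years = 2)
  expect_identical(as.data.frame(ev1), as.data.frame(ev2))
  expect_true(all(ev1$auc >= 0 & ev1$auc <= 1, na.rm = TRUE))

  # permuted outcomes: mean AUC within 0.5 +/- 0.05
  set.seed(77)
  co_perm <- co
  for (cc in c("TBI", "PTSD", "Depr"))
    for (y in 2:5) {
      col <- paste0(cc, "_Y", y)
      co_perm[[col]] <- sample(co_perm[[col]])
    }
  evp <- cross_validate(co_perm, function(train) fit_cpts(net$graph, train),
                        k = 4, seed = 9, years = 2)
  expect_lt(abs(mean(evp$auc, na.rm = TRUE) - 0.5), 0.05)

  expect_error(cross_validate(co, pipe, k = 1, seed = 1), "k must be >= 2")
  expect_error(cross_validate(co[1:3, ], pipe, k = 10, seed = 1),
               "more folds")
})

test_that("strong-signal cohorts give high year-2 AUC for the true model", {
  spec <- bn_spec_recovery(persistence = 5, cross_effect = 2.5)
  spec$prevalence[] <- 0.3
  spec$onset[] <- 0.02
  net <- make_ground_truth(spec)
  co <- sample_cohort(net, 10000, seed = 7)
  ev <- cross_validate(co, function(train) fit_cpts(net$graph, train),
                       k = 5, seed = 7, years = 2)
  means <- attr(ev, "means")
  expect_true(all(means$auc[means$year == 2] > 0.9))
})
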