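small_cfg <- function(seed, ...) {
  p1_config(n_iter = 800, burn_in = 300, seed = seed, ...)
}

test_that("denser networks pull the density parameter up", {
  g <- 8
  empty <- make_net(matrix(0L, g, g), "resistant")
  full <- make_net(1L - diag(g), "parental")
  fit <- gibbs_fit(empty, full, small_cfg(101))
  expect_lt(mean(fit$draws$theta[, "R"]), mean(fit$draws$theta[, "P"]))
})

test_that("identical condition networks induce positively correlated propensities", {
  set.seed(41)
  adj <- matrix(0L, 6, 6)
  adj[upper.tri(adj)] <- rbinom(15, 1, 0.6)
  adj <- adj + t(adj)
  fit <- gibbs_fit(make_net(adj, "resistant"), make_net(adj, "parental"),
                   small_cfg(102))
  expect_gt(fit$diagnostics["sigma_cor", "mean"], 0)
})

test_that("covariance draws stay SPD and precision draws positive", {
  set.seed(42)
  adj <- matrix(0L, 7, 7)
  adj[upper.tri(adj)] <- rbinom(21, 1, 0.4)
  adj <- adj + t(adj)
  fit <- gibbs_fit(make_net(adj, "resistant"), make_net(adj, "parental"),
                   small_cfg(103))
  d <- fit$draws$sigma
  dets <- d[, "var_R"] * d[, "var_P"] - d[, "cov_RP"]^2
  expect_true(all(d[, "var_R"] > 0 & d[, "var_P"] > 0 & dets > 0))
  expect_true(all(fit$draws$tau > 0))
  expect_true(all(fit$edge_prob_R >= 0 & fit$edge_prob_R <= 1))
  expect_equal(fit$edge_prob_R, t(fit$edge_prob_R))
})

test_that("fits are reproducible bit-for-bit from the seed", {
  adj <- matrix(0L, 5, 5); adj[1, 2] <- adj[2, 1] <- 1L; adj[3, 4] <- adj[4, 3] <- 1L
  a <- gibbs_fit(make_net(adj, "resistant"), make_net(adj, "parental"),
                 small_cfg(77))
  b <- gibbs_fit(make_net(adj, "resistant"), make_net(adj, "parental"),
                 small_cfg(77))
  expect_identical(a$draws, b$draws)
  expect_identical(a$edge_prob_R, b$edge_prob_R)
  c_mh <- gibbs_fit(make_net(adj, "resistant"), make_net(adj, "parental"),
                    small_cfg(77, sampler = "metropolis_within_gibbs"))
  d_mh <- gibbs_fit(make_net(adj, "resistant"), make_net(adj, "parental"),
                    small_cfg(77, sampler = "metropolis_within_gibbs"))
  expect_identical(c_mh$draws, d_mh$draws)
})

test_that("gene relabelling permutes the posterior edge probabilities", {
  set.seed(44)
  g <- 6
  adj <- matrix(0L, g, g)
  adj[upper.tri(adj)] <- rbinom(15, 1, 0.5)
  adj <- adj + t(adj)
  ids <- sprintf("g%02d", 1:g)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  fit1 <- gibbs_fit(make_net(adj, "resistant", ids),
                    make_net(adj * 0L, "parental", ids), small_cfg(55))
  fit2 <- gibbs_fit(make_net(adj[perm, perm], "resistant", ids[perm]),
                    make_net(adj[perm, perm] * 0L, "parental", ids[perm]),
                    small_cfg(55))
  # Monte-Carlo equivariance: permuted posterior matches within sampling error
  expect_lt(max(abs(fit2$edge_prob_R[ids, ids] - fit1$edge_prob_R)), 0.12)
  # exact equivariance holds for the deterministic grid posterior (g = 4)
  adj4 <- adj[1:4, 1:4]; ids4 <- ids[1:4]; perm4 <- c(2L, 4L, 1L, 3L)
  coarse <- list(theta = list(lower = -3, upper = 3, step = 1),
                 alpha = list(lower = -3, upper = 3, step = 1))
  bf1 <- brute_force_posterior(make_net(adj4, "resistant", ids4),
                               make_net(adj4 * 0L, "parental", ids4),
                               grid = coarse)
  bf2 <- brute_force_posterior(make_net(adj4[perm4, perm4], "resistant",
                                        ids4[perm4]),
                               make_net(adj4[perm4, perm4] * 0L, "parental",
                                        ids4[perm4]),
                               grid = coarse)
  expect_equal(bf2$R[ids4, ids4], bf1$R, tolerance = 1e-10)
})

test_that("mismatched gene lists are rejected", {
  a <- make_net(matrix(0L, 3, 3), ids = c("x", "y", "z"))
  b <- make_net(matrix(0L, 3, 3), ids = c("x", "y", "w"))
  expect_error(gibbs_fit(a, b, small_cfg(1)), "same gene list")
})

test_that("edge probability estimators agree within binomial error", {
  adj <- matrix(0L, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1L
  fit <- gibbs_fit(make_net(adj, "resistant"), make_net(adj, "parental"),
                   p1_config(n_iter = 1300, burn_in = 300, seed = 9))
  pm <- posterior_edge_probs(fit, "mean")
  pd <- posterior_edge_probs(fit, "draws", seed = 4)
  n <- nrow(fit$draws$theta)
  se <- sqrt(pm$R * (1 - pm$R) / n)
  ut <- upper.tri(pm$R)
  expect_true(all(abs(pd$R - pm$R)[ut] <= 3 * se[ut] + 1e-9))
})

test_that("a single zero-parameter draw gives 0.5 everywhere (mean estimator)", {
  fake <- list(draws = list(theta = matrix(0, 1, 2, dimnames = list(NULL, c("R", "P"))),
                            tau = matrix(1, 1, 2),
                            alpha = array(0, c(1, 4, 2),
                                          dimnames = list(NULL, NULL, c("R", "P"))),
                            sigma = matrix(c(1, 1, 0), 1, 3)),
               gene_ids = letters[1:4])
  ep <- posterior_edge_probs(fake, "mean")
  expect_true(all(ep$R[upper.tri(ep$R)] == 0.5))
  # draws estimator concentrates around 0.5 given many retained iterations
  fake2 <- fake
  fake2$draws$theta <- matrix(0, 1000, 2, dimnames = list(NULL, c("R", "P")))
  fake2$draws$alpha <- array(0, c(1000, 4, 2),
                             dimnames = list(NULL, NULL, c("R", "P")))
  ep2 <- posterior_edge_probs(fake2, "draws", seed = 10)
  expect_true(all(abs(ep2$R[upper.tri(ep2$R)] - 0.5) < 0.05))
  expect_error(posterior_edge_probs(list(draws = list(theta = NULL)), "mean"),
               "zero retained")
})
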