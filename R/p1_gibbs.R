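#' Jointly fit the undirected p1-model to two condition networks
#'
#' Fits the hierarchical Bayesian p1-model to the resistant and parental
#' relationship networks in one joint MCMC run. Each condition has its own
#' density parameter `theta` (normal prior, Gamma-hyperprior precision) and
#' per-gene propensities `alpha`; a gene's (resistant, parental) propensity
#' pair is bivariate normal with covariance `Sigma` (Wishart prior on its
#' inverse), which is the only coupling between the two conditions: the
#' resistant likelihood sees only `network_R`, the parental likelihood only
#' `network_P`.
#'
#' The default sampler augments every dyad with a Polya-Gamma variable so that
#' all `alpha` and `theta` updates are exact conjugate Gaussian draws; the
#' alternative is an adaptive Metropolis-within-Gibbs random walk. Per sweep
#' the updates are: Polya-Gamma latents and the `alpha` vector of each
#' condition (one Gaussian block per condition, given the other condition's
#' `alpha` through `Sigma`), then `theta_R`, `theta_P`, their precisions
#' `tau`, and `solve(Sigma)` from its Wishart full conditional with degrees of
#' freedom `wishart_df + g` and scale `solve(wishart_scale + crossprod(A))`
#' (R's [stats::rWishart()] scale convention), where `A` is the g x 2 matrix
#' of propensity pairs.
#'
#' @param network_R,network_P `RelationshipNetwork`s over the same genes in
#'   the same order (resistant and parental).
#' @param config a [p1_config()].
#' @return object of class `P1Posterior`: list with
#'   \describe{
#'     \item{draws}{retained parameter draws: `theta` (n x 2, columns R/P),
#'       `tau` (n x 2), `alpha` (n x g x 2 array, slices R/P), `sigma`
#'       (n x 3: variances and covariance).}
#'     \item{edge_prob_R, edge_prob_P}{symmetric g x g posterior edge
#'       probability matrices in `[0, 1]`.}
#'     \item{diagnostics}{data.frame of mean, sd and effective sample size per
#'       scalar parameter.}
#'   }
#' @export
gibbs_fit <- function(network_R, network_P, config) {
  stopifnot(inherits(config, "P1Config"))
  if (!identical(network_R$gene_ids, network_P$gene_ids))
    stop("the two networks must share the same gene list in the same order")
  g <- length(network_R$gene_ids)
  set.seed(config$seed)
  state <- p1_init_state(g, config)
  fit <- if (config$sampler == "polya_gamma")
    p1_run_pg(network_R, network_P, config, state)
  else
    p1_run_mh(network_R, network_P, config, state)
  fit$gene_ids <- network_R$gene_ids
  ep <- posterior_edge_probs(fit, estimator = config$edge_prob_estimator)
  fit$edge_prob_R <- ep$R
  fit$edge_prob_P <- ep$P
  fit$diagnostics <- p1_diagnostics(fit)
  fit$config <- config
  class(fit) <- "P1Posterior"
  fit
}

p1_init_state <- function(g, config) {
  sigma <- if (is.null(config$fix_sigma)) diag(2) else config$fix_sigma
  dimnames(sigma) <- list(c("R", "P"), c("R", "P"))
  list(theta = c(R = 0, P = 0),
       tau = c(R = if (is.null(config$fix_tau_theta)) 1 else config$fix_tau_theta,
               P = if (is.null(config$fix_tau_theta)) 1 else config$fix_tau_theta),
       alpha = matrix(0, g, 2, dimnames = list(NULL, c("R", "P"))),
       sigma = sigma)
}

p1_alloc_draws <- function(n_keep, g) {
  list(theta = matrix(NA_real_, n_keep, 2, dimnames = list(NULL, c("R", "P"))),
       tau = matrix(NA_real_, n_keep, 2, dimnames = list(NULL, c("R", "P"))),
       alpha = array(NA_real_, c(n_keep, g, 2),
                     dimnames = list(NULL, NULL, c("R", "P"))),
       sigma = matrix(NA_real_, n_keep, 3,
                      dimnames = list(NULL, c("var_R", "var_P", "cov_RP"))))
}

p1_check_finite <- function(state, it) {
  if (!all(is.finite(state$theta)) || !all(is.finite(state$alpha)) ||
      !all(is.finite(state$sigma)) || !all(is.finite(state$tau)))
    stop("non-finite sampler state at iteration ", it)
  invisible(TRUE)
}

# shared conjugate updates -------------------------------------------------

p1_update_tau <- function(state, config) {
  if (is.null(config$fix_tau_theta)) {
    state$tau["R"] <- rgamma(1, config$a0 + 0.5,
                             config$b0 + state$theta["R"]^2 / 2)
    state$tau["P"] <- rgamma(1, config$a0 + 0.5,
                             config$b0 + state$theta["P"]^2 / 2)
  }
  state
}

p1_update_sigma <- function(state, config) {
  if (is.null(config$fix_sigma)) {
    g <- nrow(state$alpha)
    rate <- config$wishart_scale + crossprod(state$alpha)
    prec <- rWishart(1, df = config$wishart_df + g, Sigma = solve(rate))[, , 1]
    sig <- solve(prec)
    sig <- (sig + t(sig)) / 2
    dimnames(sig) <- list(c("R", "P"), c("R", "P"))
    state$sigma <- sig
  }
  state
}

# Polya-Gamma augmented sampler ---------------------------------------------

p1_run_pg <- function(network_R, network_P, config, state) {
  g <- nrow(state$alpha)
  ut <- which(upper.tri(diag(g)), arr.ind = TRUE)
  ii <- ut[, 1L]; jj <- ut[, 2L]
  kappa <- list(R = network_R$adjacency[upper.tri(diag(g))] - 0.5,
                P = network_P$adjacency[upper.tri(diag(g))] - 0.5)
  n_keep <- config$n_iter - config$burn_in
  draws <- p1_alloc_draws(n_keep, g)
  other <- c(R = "P", P = "R")
  for (it in seq_len(config$n_iter)) {
    for (cc in c("R", "P")) {
      a <- state$alpha[, cc]
      eta <- state$theta[cc] + a[ii] + a[jj]
      omega <- rpg_devroye(eta)
      # conditional prior of alpha^cc given the other condition's alpha
      s <- state$sigma
      rho_slope <- s[cc, other[cc]] / s[other[cc], other[cc]]
      cond_var <- s[cc, cc] - s[cc, other[cc]]^2 / s[other[cc], other[cc]]
      prior_mean <- rho_slope * state$alpha[, other[cc]]
      # Gaussian block update of the whole alpha vector
      w <- matrix(0, g, g)
      w[ut] <- omega; w <- w + t(w)
      q <- w
      diag(q) <- rowSums(w) + 1 / cond_var
      km <- matrix(0, g, g)
      km[ut] <- kappa[[cc]] - omega * state$theta[cc]
      km <- km + t(km)
      b <- rowSums(km) + prior_mean / cond_var
      ch <- chol(q)
      mu <- backsolve(ch, forwardsolve(t(ch), b))
      state$alpha[, cc] <- mu + backsolve(ch, rnorm(g))
      # theta update with the same augmentation
      a <- state$alpha[, cc]
      asum <- a[ii] + a[jj]
      prec <- state$tau[cc] + sum(omega)
      mean_th <- sum(kappa[[cc]] - omega * asum) / prec
      state$theta[cc] <- rnorm(1, mean_th, sqrt(1 / prec))
    }
    state <- p1_update_tau(state, config)
    state <- p1_update_sigma(state, config)
    p1_check_finite(state, it)
    if (it > config$burn_in) {
      k <- it - config$burn_in
      draws$theta[k, ] <- state$theta
      draws$tau[k, ] <- state$tau
      draws$alpha[k, , ] <- state$alpha
      draws$sigma[k, ] <- c(state$sigma[1, 1], state$sigma[2, 2],
                            state$sigma[1, 2])
    }
  }
  list(draws = draws)
}

# Metropolis-within-Gibbs fallback -------------------------------------------

p1_run_mh <- function(network_R, network_P, config, state) {
  g <- nrow(state$alpha)
  nets <- list(R = network_R, P = network_P)
  n_keep <- config$n_iter - config$burn_in
  draws <- p1_alloc_draws(n_keep, g)
  other <- c(R = "P", P = "R")
  # adaptive log step sizes (Robbins-Monro toward 0.44 acceptance)
  ls_theta <- c(R = log(0.5), P = log(0.5))
  ls_alpha <- matrix(log(0.5), g, 2, dimnames = list(NULL, c("R", "P")))
  target <- 0.44
  for (it in seq_len(config$n_iter)) {
    adapt <- it <= config$burn_in
    gam <- 1 / sqrt(it)
    for (cc in c("R", "P")) {
      adj <- nets[[cc]]$adjacency
      a <- state$alpha[, cc]
      # theta: random-walk on the full Bernoulli likelihood
      th <- state$theta[cc]
      th_new <- th + rnorm(1, 0, exp(ls_theta[cc]))
      ll_old <- p1_loglik_theta(adj, th, a)
      ll_new <- p1_loglik_theta(adj, th_new, a)
      lr <- (ll_new - ll_old) - state$tau[cc] * (th_new^2 - th^2) / 2
      acc <- log(runif(1)) < lr
      if (acc) state$theta[cc] <- th_new
      if (adapt) ls_theta[cc] <- ls_theta[cc] + gam * ((acc * 1) - target)
      # single-site alpha updates
      s <- state$sigma
      rho_slope <- s[cc, other[cc]] / s[other[cc], other[cc]]
      cond_var <- s[cc, cc] - s[cc, other[cc]]^2 / s[other[cc], other[cc]]
      th <- state$theta[cc]
      for (i in seq_len(g)) {
        a <- state$alpha[, cc]
        ai_new <- a[i] + rnorm(1, 0, exp(ls_alpha[i, cc]))
        eta_old <- th + a[i] + a[-i]
        eta_new <- th + ai_new + a[-i]
        u_i <- adj[i, -i]
        ll_old <- sum(u_i * plogis(eta_old, log.p = TRUE) +
                        (1 - u_i) * plogis(-eta_old, log.p = TRUE))
        ll_new <- sum(u_i * plogis(eta_new, log.p = TRUE) +
                        (1 - u_i) * plogis(-eta_new, log.p = TRUE))
        m_i <- rho_slope * state$alpha[i, other[cc]]
        lr <- (ll_new - ll_old) -
          ((ai_new - m_i)^2 - (a[i] - m_i)^2) / (2 * cond_var)
        acc <- log(runif(1)) < lr
        if (acc) state$alpha[i, cc] <- ai_new
        if (adapt) ls_alpha[i, cc] <- ls_alpha[i, cc] + gam * ((acc * 1) - target)
      }
    }
    state <- p1_update_tau(state, config)
    state <- p1_update_sigma(state, config)
    p1_check_finite(state, it)
    if (it > config$burn_in) {
      k <- it - config$burn_in
      draws$theta[k, ] <- state$theta
      draws$tau[k, ] <- state$tau
      draws$alpha[k, , ] <- state$alpha
      draws$sigma[k, ] <- c(state$sigma[1, 1], state$sigma[2, 2],
                            state$sigma[1, 2])
    }
  }
  list(draws = draws)
}

p1_loglik_theta <- function(adj, theta, alpha) {
  ut <- upper.tri(adj)
  eta <- theta + outer(alpha, alpha, "+")[ut]
  u <- adj[ut]
  sum(u * plogis(eta, log.p = TRUE) + (1 - u) * plogis(-eta, log.p = TRUE))
}

# posterior summaries ---------------------------------------------------------

#' Posterior edge probability matrices from retained draws
#'
#' `estimator = "draws"` implements the replicated-network rule: per retained
#' iteration, draw each dyad's edge indicator as an independent Bernoulli with
#' its dyad probability and report the per-dyad proportion of sampled networks
#' containing the edge. `estimator = "mean"` averages the dyad probabilities
#' over iterations directly (same expectation, lower Monte-Carlo variance).
#'
#' @param fit a `P1Posterior` (or the internal draws list).
#' @param estimator `"mean"` or `"draws"`.
#' @param seed optional seed for the `"draws"` coin flips (defaults to the
#'   current RNG stream).
#' @return list with symmetric matrices `R` and `P` in `[0, 1]`.
#' @export
posterior_edge_probs <- function(fit, estimator = c("mean", "draws"),
                                 seed = NULL) {
  estimator <- match.arg(estimator)
  draws <- fit$draws
  n_keep <- nrow(draws$theta)
  if (is.null(n_keep) || n_keep == 0L) stop("zero retained draws")
  if (!is.null(seed)) set.seed(seed)
  g <- dim(draws$alpha)[2L]
  acc <- list(R = matrix(0, g, g), P = matrix(0, g, g))
  for (k in seq_len(n_keep)) {
    for (cc in c("R", "P")) {
      a <- draws$alpha[k, , cc]
      p <- plogis(draws$theta[k, cc] + outer(a, a, "+"))
      if (estimator == "draws") {
        ut <- upper.tri(p)
        e <- matrix(0, g, g)
        e[ut] <- rbinom(sum(ut), 1L, p[ut])
        p <- e + t(e)
      }
      acc[[cc]] <- acc[[cc]] + p
    }
  }
  out <- lapply(acc, function(m) {
    m <- m / n_keep
    diag(m) <- 0
    dimnames(m) <- list(fit$gene_ids, fit$gene_ids)
    m
  })
  out
}

#' @export
print.P1Posterior <- function(x, ...) {
  n <- nrow(x$draws$theta)
  cat(sprintf("P1Posterior: %d genes, %d retained draws (%s sampler)\n",
              dim(x$draws$alpha)[2L], n, x$config$sampler))
  print(x$diagnostics[c("theta_R", "theta_P", "sigma_cor"), ], digits = 3)
  invisible(x)
}

# effective sample size via initial positive sequence of autocorrelations
ess <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] <= 0) break
    s <- s + rho[k]
  }
  max(1, n / (1 + 2 * s))
}

p1_diagnostics <- function(fit) {
  d <- fit$draws
  sig_cor <- d$sigma[, "cov_RP"] / sqrt(d$sigma[, "var_R"] * d$sigma[, "var_P"])
  scalars <- list(theta_R = d$theta[, "R"], theta_P = d$theta[, "P"],
                  tau_R = d$tau[, "R"], tau_P = d$tau[, "P"],
                  sigma_var_R = d$sigma[, "var_R"],
                  sigma_var_P = d$sigma[, "var_P"],
                  sigma_cov_RP = d$sigma[, "cov_RP"],
                  sigma_cor = sig_cor,
                  alpha_mean_R = rowMeans(d$alpha[, , "R", drop = FALSE]),
                  alpha_mean_P = rowMeans(d$alpha[, , "P", drop = FALSE]))
  data.frame(mean = vapply(scalars, mean, 0),
             sd = vapply(scalars, sd, 0),
             ess = vapply(scalars, ess, 0))
}

#' Credible interval for a scalar parameter of a fit
#' @param fit a `P1Posterior`.
#' @param param one of `"theta_R"`, `"theta_P"`, `"sigma_cor"`.
#' @param level interval mass (default 0.9), equal-tailed.
#' @return numeric length-2 vector (lower, upper).
#' @export
credible_interval <- function(fit, param = c("theta_R", "theta_P", "sigma_cor"),
                              level = 0.9) {
  param <- match.arg(param)
  d <- fit$draws
  x <- switch(param,
              theta_R = d$theta[, "R"], theta_P = d$theta[, "P"],
              sigma_cor = d$sigma[, "cov_RP"] /
                sqrt(d$sigma[, "var_R"] * d$sigma[, "var_P"]))
  unname(quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2)))
}
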