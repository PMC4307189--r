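#' Dyad edge probability of the undirected p1-model
#'
#' Each gene pair (dyad) carries two indicators, edge-absent and edge-present,
#' whose log-probabilities are a shared per-dyad normalizer and the normalizer
#' plus the linear predictor `theta + alpha_i + alpha_j`. Eliminating the
#' normalizer under the sum-to-one constraint gives the logistic closed form
#' returned here: `exp(eta) / (1 + exp(eta))` with
#' `eta = theta + alpha_i + alpha_j`. The complement (edge absent) is exactly
#' `1 - edge_probability(...)`.
#'
#' @param theta global density parameter (log-odds offset).
#' @param alpha_i,alpha_j per-gene propensity (expansiveness/attractiveness)
#'   parameters. All three arguments recycle like ordinary arithmetic.
#' @return probability in (0, 1); numerically stable over `|eta|` up to ~700.
#' @export
edge_probability <- function(theta, alpha_i, alpha_j) {
  eta <- theta + alpha_i + alpha_j
  if (any(!is.finite(eta) & !is.infinite(eta))) stop("non-finite linear predictor")
  plogis(eta)
}

#' Bernoulli log-likelihood of a network under the p1-model
#'
#' Sum over dyads i < j of `u_ij * log p_ij + (1 - u_ij) * log(1 - p_ij)` with
#' `p_ij = edge_probability(theta, alpha_i, alpha_j)`, computed on the log
#' scale so it stays finite for any finite parameters.
#'
#' @param network a `RelationshipNetwork`.
#' @param theta scalar density parameter.
#' @param alpha numeric vector of per-gene propensities, one per gene.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(network, theta, alpha) {
  g <- length(network$gene_ids)
  if (length(alpha) != g) stop("'alpha' must have one entry per gene")
  ut <- upper.tri(network$adjacency)
  eta <- theta + outer(alpha, alpha, "+")[ut]
  u <- network$adjacency[ut]
  # log p = plogis(eta, log=TRUE); log(1-p) = plogis(-eta, log=TRUE)
  sum(u * plogis(eta, log.p = TRUE) + (1 - u) * plogis(-eta, log.p = TRUE))
}

#' Configuration of the joint p1-model fit
#'
#' Defaults are deliberately conservative screening settings: 6000 total iterations with
#' the first 5000 discarded as burn-in (1000 retained networks), a
#' Gamma(0.001, 0.001) hyperprior on each theta precision, and a Wishart prior
#' with identity scale and 2 degrees of freedom on the inverse of the 2x2
#' covariance coupling each gene's (resistant, parental) propensity pair.
#'
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded before retaining draws
#'   (`n_iter - burn_in >= 100`).
#' @param seed integer random seed (mandatory: every fit is reproducible).
#' @param a0,b0 shape and rate of the Gamma hyperprior on the theta precisions.
#' @param wishart_df,wishart_scale prior degrees of freedom (>= 2) and 2x2
#'   symmetric positive-definite scale matrix of the Wishart prior on
#'   `solve(Sigma)` (rate parameterization: the prior density carries
#'   `exp(-tr(scale %*% W) / 2)`).
#' @param edge_prob_estimator `"mean"` (average of dyad probabilities over
#'   retained draws) or `"draws"` (proportion of retained sampled networks
#'   containing the edge — the replicated-network rule).
#' @param sampler `"polya_gamma"` (exact conjugate Gibbs via Polya-Gamma
#'   augmentation, default) or `"metropolis_within_gibbs"` (adaptive
#'   random-walk fallback).
#' @param fix_sigma optional 2x2 SPD matrix: hold Sigma fixed (no Wishart
#'   update); used by the small-instance oracle comparisons.
#' @param fix_tau_theta optional positive scalar: hold both theta precisions
#'   fixed (no Gamma update).
#' @return list of class `P1Config`.
#' @export
p1_config <- function(n_iter = 6000L, burn_in = 5000L, seed,
                      a0 = 0.001, b0 = 0.001,
                      wishart_df = 2, wishart_scale = diag(2),
                      edge_prob_estimator = c("mean", "draws"),
                      sampler = c("polya_gamma", "metropolis_within_gibbs"),
                      fix_sigma = NULL, fix_tau_theta = NULL) {
  if (missing(seed)) stop("'seed' is mandatory for reproducible fits")
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (n_iter <= 0L || burn_in < 0L || burn_in >= n_iter)
    stop("need 0 <= burn_in < n_iter")
  if (n_iter - burn_in < 100L)
    stop("need at least 100 retained iterations (n_iter - burn_in >= 100)")
  if (a0 <= 0 || b0 <= 0) stop("'a0' and 'b0' must be positive")
  if (wishart_df < 2) stop("'wishart_df' must be >= 2")
  check_spd2(wishart_scale, "wishart_scale")
  if (!is.null(fix_sigma)) check_spd2(fix_sigma, "fix_sigma")
  if (!is.null(fix_tau_theta) && fix_tau_theta <= 0)
    stop("'fix_tau_theta' must be positive")
  structure(list(n_iter = n_iter, burn_in = burn_in, seed = as.integer(seed),
                 a0 = a0, b0 = b0, wishart_df = wishart_df,
                 wishart_scale = wishart_scale,
                 edge_prob_estimator = match.arg(edge_prob_estimator),
                 sampler = match.arg(sampler),
                 fix_sigma = fix_sigma, fix_tau_theta = fix_tau_theta),
            class = "P1Config")
}

check_spd2 <- function(m, name) {
  if (!is.matrix(m) || !identical(dim(m), c(2L, 2L)))
    stop("'", name, "' must be a 2x2 matrix")
  if (max(abs(m - t(m))) > 1e-10) stop("'", name, "' must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'", name, "' must be positive-definite")
  invisible(TRUE)
}
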