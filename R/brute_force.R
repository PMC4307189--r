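#' Grid-based posterior edge probabilities for tiny networks
#'
#' Small-instance oracle: computes posterior edge probabilities by direct
#' summation of likelihood x prior over a regular parameter grid, normalized.
#' Requires `g <= 4` genes and a *diagonal* fixed `Sigma`: with the coupling
#' covariance held diagonal the two conditions decouple, so each condition's
#' posterior over `(theta, alpha_1, ..., alpha_g)` is an exact (1 + g)-
#' dimensional grid sum. The theta prior standard deviation is likewise fixed
#' (no hyperprior), matching a [gibbs_fit()] run with `fix_sigma` and
#' `fix_tau_theta` set. Intended for tests only.
#'
#' @param network_R,network_P `RelationshipNetwork`s over the same `<= 4`
#'   genes.
#' @param grid list with elements `theta` (bounds + step for theta), `alpha`
#'   (bounds + step for every alpha), each a list `lower`, `upper`, `step`.
#' @param sigma_alpha fixed prior standard deviation of every alpha (the
#'   square root of the diagonal Sigma entry).
#' @param sigma_theta fixed prior standard deviation of theta.
#' @return list with matrices `R` and `P` of posterior edge probabilities.
#' @export
brute_force_posterior <- function(network_R, network_P,
                                  grid = list(theta = list(lower = -5, upper = 5, step = 0.5),
                                              alpha = list(lower = -5, upper = 5, step = 0.5)),
                                  sigma_alpha = 1, sigma_theta = 1) {
  if (!identical(network_R$gene_ids, network_P$gene_ids))
    stop("the two networks must share the same gene list")
  g <- length(network_R$gene_ids)
  if (g > 4L) stop("brute-force oracle supports g <= 4 only")
  gt <- seq(grid$theta$lower, grid$theta$upper, by = grid$theta$step)
  ga <- seq(grid$alpha$lower, grid$alpha$upper, by = grid$alpha$step)
  out <- list(
    R = bf_one_condition(network_R$adjacency, gt, ga, sigma_alpha, sigma_theta),
    P = bf_one_condition(network_P$adjacency, gt, ga, sigma_alpha, sigma_theta))
  for (cc in c("R", "P"))
    dimnames(out[[cc]]) <- list(network_R$gene_ids, network_R$gene_ids)
  out
}

bf_one_condition <- function(adj, grid_theta, grid_alpha, sigma_alpha,
                             sigma_theta) {
  g <- nrow(adj)
  cols <- c(list(theta = grid_theta),
            rep(list(grid_alpha), g))
  names(cols)[-1L] <- paste0("a", seq_len(g))
  pts <- as.matrix(expand.grid(cols, KEEP.OUT.ATTRS = FALSE))
  logp <- dnorm_log_sum(pts[, 1L], sigma_theta)
  for (i in seq_len(g))
    logp <- logp + dnorm_log_sum(pts[, i + 1L], sigma_alpha)
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  eta_list <- vector("list", nrow(ut))
  for (d in seq_len(nrow(ut))) {
    i <- ut[d, 1L]; j <- ut[d, 2L]
    eta <- pts[, 1L] + pts[, i + 1L] + pts[, j + 1L]
    eta_list[[d]] <- eta
    logp <- logp + if (adj[i, j] == 1L) plogis(eta, log.p = TRUE)
    else plogis(-eta, log.p = TRUE)
  }
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  ep <- matrix(0, g, g)
  for (d in seq_len(nrow(ut))) {
    i <- ut[d, 1L]; j <- ut[d, 2L]
    ep[i, j] <- ep[j, i] <- sum(w * plogis(eta_list[[d]]))
  }
  ep
}

dnorm_log_sum <- function(x, sd) -x^2 / (2 * sd^2)  # constants cancel
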