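#' Prior hyperparameters for the hyperexponential mixture
#'
#' Bundles the conjugate prior parameters of the Bayesian mixture model:
#' a `Gamma(alpha, beta)` prior on each component rate, and a symmetric
#' `Dirichlet(gamma)` prior on the weights. With `gamma = 1/K` the finite
#' mixture approximates a Dirichlet-process mixture, so `K` acts as an upper
#' bound on the component count rather than a model-selection choice.
#'
#' Defaults are `alpha = 1`, `beta = 3` (a broad prior that keeps support
#' near zero rates, i.e. long residence times) and `gamma = 1/K`. `beta`
#' carries units of time (ns, conjugate to rates in ns^-1): changing the
#' time unit rescales `beta` accordingly.
#'
#' @param K maximum number of mixture components.
#' @param alpha Gamma shape(s), recycled to length `K`.
#' @param beta Gamma rate(s) (ns), recycled to length `K`.
#' @param gamma Dirichlet concentration(s), recycled to length `K`.
#' @return an object of class `"hyperparameters"`: a list with vector
#'   elements `alpha`, `beta`, `gamma` of length `K`, plus `K`.
#' @export
hyperparameters <- function(K = 15, alpha = 1, beta = 3, gamma = 1 / K) {
    if (K < 1) stop("'K' must be at least 1")
    hp <- list(K = as.integer(K),
               alpha = rep_len(alpha, K),
               beta = rep_len(beta, K),
               gamma = rep_len(gamma, K))
    if (any(hp$alpha <= 0) || any(hp$beta <= 0) || any(hp$gamma <= 0))
        stop("'alpha', 'beta' and 'gamma' must all be positive")
    class(hp) <- "hyperparameters"
    hp
}

#' Conditional posterior probabilities of the component indicator
#'
#' For an observed residence time `t` the latent indicator `z` follows a
#' categorical distribution with
#' \eqn{p(z = k) \propto \pi_k \lambda_k e^{-\lambda_k t}}. Computed in log
#' space with max-subtraction so that very large \eqn{\lambda_k t} (fast
#' "flicker" components evaluated at long events) never underflows to NaN.
#'
#' @param t positive residence time(s) (ns).
#' @param weights,rates current mixture state (see [hypexp]).
#' @return for scalar `t` a probability vector of length `K`; for vector `t`
#'   a `length(t) x K` matrix whose rows sum to 1.
#' @export
indicator_probs <- function(t, weights, rates) {
    check_mixture(weights, rates)
    if (any(t <= 0)) stop("residence times must be positive")
    loga <- outer(t, rates, function(ti, lk) -lk * ti) +
        rep(log(weights) + log(rates), each = length(t))
    m <- apply(loga, 1L, max)
    p <- exp(loga - m)
    p <- p / rowSums(p)
    if (length(t) == 1L) drop(p) else p
}

#' Per-component sufficient statistics of the indicator
#'
#' Given indicator labels `z` and residence times `t`, tallies the event
#' count \eqn{\Omega_k} and total residence time
#' \eqn{T_k = \sum_n [z_n = k]\, t_n} for each component.
#'
#' @param z integer labels in `1..K`, one per event.
#' @param t residence times, same length as `z`.
#' @param K number of components.
#' @return list with numeric vectors `Omega_k` and `T_k` of length `K`.
#' @export
sufficient_stats <- function(z, t, K) {
    if (length(z) != length(t))
        stop("'z' and 't' must have the same length")
    if (any(z < 1L | z > K))
        stop("indicator labels out of range 1..", K)
    Omega_k <- tabulate(z, nbins = K)
    T_k <- numeric(K)
    sums <- rowsum(t, group = z)
    T_k[as.integer(rownames(sums))] <- sums[, 1L]
    list(Omega_k = Omega_k, T_k = T_k)
}

#' Posterior parameters of the mixture weights
#'
#' The Dirichlet prior is conjugate to the categorical indicator, so the
#' conditional posterior of the weights is
#' `Dirichlet(gamma + Omega_k)`: the hyperparameters act as pseudo-counts.
#'
#' @param stats sufficient statistics from [sufficient_stats()].
#' @param hp a [hyperparameters()] object.
#' @return Dirichlet concentration vector `gamma + Omega_k` of length `K`.
#' @export
weights_posterior <- function(stats, hp) {
    if (length(stats$Omega_k) != hp$K)
        stop("sufficient statistics and hyperparameters disagree on K")
    hp$gamma + stats$Omega_k
}

#' Posterior parameters of a component rate
#'
#' The Gamma prior is conjugate to the exponential likelihood, so the
#' conditional posterior of rate `k` is
#' `Gamma(alpha_k + Omega_k, beta_k + T_k)` (shape, rate). An empty
#' component (`Omega_k = 0`) recovers its prior.
#'
#' @param k component index in `1..K`.
#' @inheritParams weights_posterior
#' @return named numeric vector `c(shape = ..., rate = ...)`.
#' @export
rate_posterior <- function(k, stats, hp) {
    if (k < 1 || k > hp$K) stop("'k' out of range 1..", hp$K)
    c(shape = hp$alpha[k] + stats$Omega_k[k],
      rate = hp$beta[k] + stats$T_k[k])
}
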