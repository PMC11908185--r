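#' The hyperexponential distribution
#'
#' Density, survival/distribution function, and random generation for the
#' hyperexponential (mixture-of-exponentials) distribution with mixing
#' weights `weights` and component rates `rates`:
#' \deqn{p(t) = \sum_{k=1}^K \pi_k \lambda_k e^{-\lambda_k t}, \qquad
#'       S(t) = \sum_{k=1}^K \pi_k e^{-\lambda_k t}.}
#'
#' This is the waiting-time model for binding residence times composed of
#' several kinetic processes: each binding event belongs to one of `K`
#' exponential processes (e.g. a brief surface touch vs. a long-lived bound
#' pose), process `k` being chosen with probability \eqn{\pi_k} and its
#' residence time drawn from an exponential with rate \eqn{\lambda_k}.
#'
#' @param x,q vector of non-negative times (ns).
#' @param n number of draws.
#' @param weights mixing weights; must be positive and sum to 1 (within
#'   `1e-12`).
#' @param rates component rates (ns^-1); must be positive, same length as
#'   `weights`.
#' @param lower.tail if `FALSE`, `phypexp()` returns the survival function
#'   \eqn{S(t) = P(T \ge t)}.
#' @param labels if `TRUE`, `rhypexp()` also returns the latent component
#'   label of each draw (for validating inference against ground truth;
#'   labels must never be fed to the inference itself).
#'
#' @return `dhypexp()` and `phypexp()` return numeric vectors. `rhypexp()`
#'   returns a numeric vector of durations, or (with `labels = TRUE`) a list
#'   with elements `durations` and `labels`.
#'
#' @examples
#' dhypexp(0, weights = 1, rates = 2)          # 2: pdf at origin equals rate
#' phypexp(0, weights = c(.5, .5), rates = c(1, 4), lower.tail = FALSE)  # 1
#' set.seed(7)
#' t <- rhypexp(1000, weights = c(0.9, 0.1), rates = c(5, 0.1))
#' @name hypexp
NULL

check_mixture <- function(weights, rates) {
    if (length(weights) != length(rates))
        stop("'weights' and 'rates' must have the same length")
    if (any(!is.finite(weights)) || any(weights < 0))
        stop("'weights' must be finite and non-negative")
    if (abs(sum(weights) - 1) > 1e-12)
        stop("'weights' must sum to 1 (got ", format(sum(weights)), ")")
    if (any(!is.finite(rates)) || any(rates <= 0))
        stop("'rates' must be finite and positive")
    invisible(TRUE)
}

#' @rdname hypexp
#' @export
dhypexp <- function(x, weights, rates) {
    check_mixture(weights, rates)
    if (any(x < 0)) stop("negative times are outside the support")
    vapply(x, function(t) sum(weights * rates * exp(-rates * t)), numeric(1))
}

#' @rdname hypexp
#' @export
phypexp <- function(q, weights, rates, lower.tail = TRUE) {
    check_mixture(weights, rates)
    if (any(q < 0)) stop("negative times are outside the support")
    s <- vapply(q, function(t) sum(weights * exp(-rates * t)), numeric(1))
    if (lower.tail) 1 - s else s
}

#' @rdname hypexp
#' @export
rhypexp <- function(n, weights, rates, labels = FALSE) {
    check_mixture(weights, rates)
    K <- length(weights)
    z <- sample.int(K, n, replace = TRUE, prob = weights)
    t <- rexp(n, rate = rates[z])
    if (labels) list(durations = t, labels = z) else t
}
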