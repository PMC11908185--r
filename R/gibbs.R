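#' Configuration of the Gibbs sampler
#'
#' Collects sampler settings with the defaults used throughout: 110 000
#' iterations, the first 10 000 discarded as burn-in, and every 100th
#' iteration kept thereafter, giving exactly 1000 approximately independent
#' posterior samples. `K` is the upper bound on the number of mixture
#' components; with the Dirichlet concentration `gamma = 1/K` the result is
#' insensitive to `K` provided it is set comfortably above the number of
#' components supported by the data.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded from the start of the chain.
#' @param thin keep-every stride applied after burn-in.
#' @param seed integer RNG seed; recorded in the chain for replay.
#' @param K maximum number of mixture components.
#' @param alpha,beta,gamma prior hyperparameters, see [hyperparameters()].
#' @return object of class `"gibbs_config"`.
#' @export
gibbs_config <- function(n_iter = 110000, burn_in = 10000, thin = 100,
                         seed = 1L, K = 15, alpha = 1, beta = 3,
                         gamma = 1 / K) {
    if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
    if (thin < 1) stop("'thin' must be at least 1")
    if ((n_iter - burn_in) %/% thin < 1)
        stop("no samples would be kept: increase 'n_iter' or lower 'thin'")
    cfg <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                thin = as.integer(thin), seed = as.integer(seed),
                hp = hyperparameters(K, alpha, beta, gamma))
    class(cfg) <- "gibbs_config"
    cfg
}

#' @export
print.gibbs_config <- function(x, ...) {
    cat("Gibbs configuration: K =", x$hp$K,
        "| iterations", x$n_iter, "| burn-in", x$burn_in,
        "| thin", x$thin, "| seed", x$seed, "\n")
    invisible(x)
}

#' Feasible starting state for the sampler
#'
#' Uniform weights and component rates log-spaced across the reciprocal
#' range of the observed residence times, `[1/max(t), 1/min(t)]`, so every
#' timescale present in the data is reachable from the start. The posterior
#' is insensitive to the starting point; any feasible state converges to
#' the same answer after burn-in.
#'
#' @param config a [gibbs_config()].
#' @param t residence times (ns).
#' @return list with elements `weights` and `rates`.
#' @export
initialize_state <- function(config, t) {
    K <- config$hp$K
    lo <- 1 / max(t)
    hi <- 1 / min(t)
    rates <- if (K == 1L || lo == hi) rep(sqrt(lo * hi), K)
             else exp(seq(log(lo), log(hi), length.out = K))
    list(weights = rep(1 / K, K), rates = rates)
}

#' Run the Gibbs sampler for the hyperexponential mixture
#'
#' Iterates the three closed-form conditional-posterior draws: the
#' indicator of every event from its categorical conditional, the weights
#' from `Dirichlet(gamma + Omega_k)`, and each rate from
#' `Gamma(alpha_k + Omega_k, beta_k + T_k)`. After discarding `burn_in`
#' iterations and thinning, the kept samples (weights, rates, indicators)
#' form the chain used by [correct_labels()] and [membership_matrix()].
#' Runs are deterministic given `(t, config$seed)`.
#'
#' @param t positive residence times (ns), or a [residence_series()].
#' @param config a [gibbs_config()].
#' @param init optional starting state as from [initialize_state()].
#' @param store_z keep the per-sample indicator matrix (required for
#'   kinetic mapping; `w x Omega` integers).
#' @param verbose print progress every 1000 iterations.
#' @return object of class `"gibbs_chain"`: list with matrices `pi`
#'   (`w x K`), `lambda` (`w x K`), `z` (`w x Omega`, if stored), sample
#'   count `w`, the input durations `t`, `Omega`, `config`, and a
#'   `data_fingerprint` of the durations.
#' @export
run_gibbs <- function(t, config = gibbs_config(), init = NULL,
                      store_z = TRUE, verbose = FALSE) {
    if (inherits(t, "residence_series")) t <- t$durations
    if (!inherits(config, "gibbs_config")) stop("'config' must be a gibbs_config")
    if (length(t) < 1L) stop("at least one residence time required")
    bad <- which(!is.finite(t) | t <= 0)
    if (length(bad))
        stop("non-positive or non-finite residence time at index ", bad[1L])

    hp <- config$hp
    if (is.null(init)) init <- initialize_state(config, t)
    stopifnot(length(init$weights) == hp$K, length(init$rates) == hp$K)

    res <- with_local_seed(config$seed,
        gibbs_core(t, hp$K, config$n_iter, config$burn_in, config$thin,
                   hp$alpha, hp$beta, hp$gamma,
                   init$weights, init$rates, store_z, verbose))

    chain <- list(pi = res$pi, lambda = res$lambda,
                  z = if (store_z) res$z else NULL,
                  w = res$w, t = t, Omega = length(t),
                  config = config,
                  data_fingerprint = data_fingerprint(t))
    class(chain) <- "gibbs_chain"
    chain
}

# compact numeric digest of the durations, recorded in chains and manifests
# so archived results can be matched to their input data
data_fingerprint <- function(t) {
    c(n = length(t), sum = sum(t), sum_sq = sum(t^2),
      min = min(t), max = max(t))
}

#' @export
print.gibbs_chain <- function(x, ...) {
    cat("Hyperexponential-mixture Gibbs chain:",
        x$w, "kept samples, K =", x$config$hp$K,
        ", Omega =", x$Omega, "events\n")
    cat("  indicators stored:", !is.null(x$z),
        "| seed", x$config$seed, "\n")
    invisible(x)
}

#' Archive or restore a Gibbs chain
#'
#' A chain archive is a single RDS file holding the full `"gibbs_chain"`
#' object (configuration, seed, data fingerprint, and the `pi`, `lambda`,
#' `z` arrays), re-loadable for postprocessing without rerunning the
#' sampler.
#'
#' @param chain a `"gibbs_chain"`.
#' @param path file path (conventionally `.rds`).
#' @export
write_chain <- function(chain, path) {
    stopifnot(inherits(chain, "gibbs_chain"))
    saveRDS(chain, path)
    invisible(path)
}

#' @rdname write_chain
#' @return `read_chain()` returns the restored `"gibbs_chain"`.
#' @export
read_chain <- function(path) {
    chain <- readRDS(path)
    if (!inherits(chain, "gibbs_chain"))
        stop("'", path, "' does not contain a Gibbs chain archive")
    chain
}
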