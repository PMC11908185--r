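# shared fixtures, all generated in code

# Construct a gibbs_chain object directly (bypassing the sampler) so
# postprocessing can be tested against hand-built posterior samples.
fake_chain <- function(pi, lambda, z = NULL, t = NULL,
                       numerator_omega = 1000) {
    stopifnot(is.matrix(pi), all(dim(pi) == dim(lambda)))
    w <- nrow(pi)
    K <- ncol(pi)
    if (is.null(t)) t <- rexp(if (is.null(z)) 10 else ncol(z), 1)
    cfg <- gibbs_config(n_iter = w * 10 + 10, burn_in = 10, thin = 10,
                        seed = 99L, K = K)
    chain <- list(pi = pi, lambda = lambda, z = z, w = w, t = t,
                  Omega = if (is.null(z)) numerator_omega else length(t),
                  config = cfg,
                  data_fingerprint = c(n = length(t), sum = sum(t),
                                       sum_sq = sum(t^2), min = min(t),
                                       max = max(t)))
    class(chain) <- "gibbs_chain"
    chain
}

# Chain whose samples are per-sample permutations of fixed, well-separated
# (weight, rate) triples plus K - 3 negligible components, with optional
# multiplicative jitter. The true cluster of every surviving component is
# returned for oracle comparison.
permuted_chain <- function(w = 100, K = 5, seed = 42,
                           weights = c(0.90, 0.08, 0.02),
                           rates = c(5, 0.5, 0.05), jitter = 0.02) {
    set.seed(seed)
    ncomp <- length(weights)
    Omega <- 1000
    pi <- matrix(1e-6, w, K)       # background far below 10/Omega = 0.01
    lambda <- matrix(1, w, K)
    truth <- matrix(0L, w, K)
    for (i in seq_len(w)) {
        slots <- sample.int(K, ncomp)
        jit_w <- weights * exp(runif(ncomp, -jitter, jitter))
        pi[i, slots] <- jit_w / sum(jit_w) * sum(weights)
        lambda[i, slots] <- rates * exp(runif(ncomp, -jitter, jitter))
        truth[i, slots] <- seq_len(ncomp)
    }
    list(chain = fake_chain(pi, lambda, numerator_omega = Omega),
         truth = truth)
}

# Moderate-size two-component fit reused across method tests (computed once
# per test run; ~2 s)
shared_fit <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            set.seed(11)
            t <- rhypexp(2000, c(0.8, 0.2), c(5, 0.1))
            cache <<- resmix(t, K = 8, n_iter = 6000, burn_in = 1000,
                             thin = 10, seed = 5)
        }
        cache
    }
})

# apply a random within-sample permutation of component labels to a chain
permute_chain_labels <- function(chain, seed = 1) {
    set.seed(seed)
    K <- chain$config$hp$K
    out <- chain
    for (i in seq_len(chain$w)) {
        perm <- sample.int(K)
        out$pi[i, perm] <- chain$pi[i, ]
        out$lambda[i, perm] <- chain$lambda[i, ]
        if (!is.null(chain$z)) out$z[i, ] <- perm[chain$z[i, ]]
    }
    out
}
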