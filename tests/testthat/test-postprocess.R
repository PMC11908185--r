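test_that("weight filter keeps components with >= 10 expected events", {
    expect_false(2L %in% filter_weights(c(0.9, 0.005), Omega = 1000))
    expect_true(2L %in% filter_weights(c(0.9, 0.01), Omega = 1000))  # boundary
    w <- c(0.5, 0.4, 0.1, 1e-4, 1e-5)
    expect_equal(filter_weights(w, Omega = 100), 1:3)
    expect_error(filter_weights(0.5, Omega = 0), "positive")
})

test_that("component count is the posterior mode with upward ties", {
    mk <- function(counts) {
        # one sample per entry; `counts` big weights plus tiny background
        pi <- t(vapply(counts, function(k)
            c(rep(0.5 / k, k), rep(1e-6, 8 - k)) /
                sum(c(rep(0.5 / k, k), rep(1e-6, 8 - k))), numeric(8)))
        fake_chain(pi, matrix(1, nrow(pi), 8), numerator_omega = 1000)
    }
    expect_equal(mode_component_count(mk(rep(3, 5))), 3L)
    expect_equal(mode_component_count(
        mk(rep(c(3, 4, 5), c(600, 300, 100)))), 3L)
    expect_equal(mode_component_count(mk(rep(c(3, 4), c(500, 500)))), 4L)
})

test_that("MAP estimate is the histogram mode with percentile interval", {
    expect_error(map_estimate(rnorm(19)), "at least 20")

    est <- map_estimate(rep(2, 50))
    expect_equal(est$map, 2)
    expect_equal(est$ci, c(2, 2))

    # Gamma(101, 53): analytic mode 100/53, recovered to histogram
    # resolution (the mode of a histogram wanders over a few bins)
    set.seed(33)
    x <- rgamma(1e6, shape = 101, rate = 53)
    est <- map_estimate(x)
    binw <- 2 * IQR(x) / length(x)^(1 / 3)
    expect_lt(abs(est$map - 100 / 53), 4 * binw)
    expect_equal(est$ci, unname(quantile(x, c(0.025, 0.975))))

    # symmetric bimodal: MAP lands in the lower mode's bin, flagged
    est <- map_estimate(rep(c(1, 3), each = 100))
    expect_lt(est$map, 2)
    expect_true(est$multimodal)
})

test_that("tau posterior transforms rates with the Jacobian-aware mode", {
    est <- tau_posterior(rep(2, 30))
    expect_equal(est$map, 0.5)

    # Gamma(alpha, beta) rates -> InverseGamma(alpha, beta) taus,
    # mode beta / (alpha + 1)
    set.seed(34)
    lam <- rgamma(1e6, shape = 5, rate = 2)
    est <- tau_posterior(lam)
    tau <- 1 / lam
    binw <- 2 * IQR(tau) / length(tau)^(1 / 3)
    expect_lt(abs(est$map - 2 / (5 + 1)), 4 * binw)

    # CI endpoints are reciprocals of the swapped rate interval (exact)
    ci_rate <- unname(quantile(lam, c(0.025, 0.975)))
    expect_identical(est$ci, unname(1 / rev(ci_rate)))
    expect_error(tau_posterior(c(1, 0)), "positive")
})

test_that("parameter-space clustering undoes label switching exactly", {
    pc <- permuted_chain(w = 120, K = 5, seed = 42)
    model <- correct_labels(pc$chain)
    expect_equal(model$K_prime, 3L)

    # oracle: the known slot of each surviving component, re-indexed by
    # decreasing rate (truth already ordered fast -> slow)
    surv <- which(t(pc$chain$pi >= 10 / pc$chain$Omega))
    K <- 5
    comp <- (surv - 1L) %% K + 1L
    samp <- (surv - 1L) %/% K + 1L
    expect_equal(model$assignment[cbind(samp, comp)],
                 pc$truth[cbind(samp, comp)])

    # every surviving (sample, component) pair lands in exactly one cluster
    sizes <- vapply(model$clusters, function(cc) length(cc$lambda),
                    integer(1))
    expect_equal(sum(sizes), length(surv))
    # permutation symmetry: all samples survive in every cluster
    expect_equal(sizes, rep(120L, 3))

    # clusters are ordered fastest to slowest
    expect_true(all(diff(model$map_lambda) < 0))
    expect_equal(model$map_lambda, c(5, 0.5, 0.05), tolerance = 0.05)
})

test_that("membership matrix matches the per-sample counting loop", {
    set.seed(44)
    w <- 20; Omega <- 5; K <- 4; Kp <- 2
    z <- matrix(sample.int(K, w * Omega, replace = TRUE), w, Omega)
    assignment <- matrix(sample(0:Kp, w * K, replace = TRUE), w, K)
    pi <- matrix(0.25, w, K)
    chain <- fake_chain(pi, matrix(1, w, K), z = z, t = rexp(Omega))
    model <- structure(list(K_prime = Kp, assignment = assignment),
                       class = "cluster_model")
    p <- membership_matrix(chain, model)

    oracle <- matrix(0, Omega, Kp)
    for (i in seq_len(w)) for (n in seq_len(Omega)) {
        cl <- assignment[i, z[i, n]]
        if (cl > 0) oracle[n, cl] <- oracle[n, cl] + 1 / w
    }
    expect_equal(unclass(p), oracle, ignore_attr = TRUE)
    expect_true(all(rowSums(p) <= 1 + 1e-12))
    expect_equal(attr(p, "unassigned"), 1 - rowSums(p))

    # single sample, single cluster
    chain1 <- fake_chain(matrix(1, 1, 1), matrix(1, 1, 1),
                         z = matrix(1L, 1, 3), t = rexp(3))
    model1 <- structure(list(K_prime = 1L,
                             assignment = matrix(1L, 1, 1)),
                        class = "cluster_model")
    expect_equal(as.vector(membership_matrix(chain1, model1)), rep(1, 3))
})

test_that("noise flagging follows the membership-maximum rule", {
    model <- structure(list(K_prime = 3L, noise = rep(FALSE, 3),
                            noise_checked = FALSE,
                            map_tau = c(0.1, 1, 10),
                            ci_tau = matrix(1:6, 3, 2)),
                       class = "cluster_model")
    p <- cbind(c(0.8, 0.7), c(0.39, 0.2), c(0.41, 0.1))
    out <- remove_noise(model, p)
    expect_equal(out$noise, c(FALSE, TRUE, FALSE))  # 0.39 noise, 0.41 kept

    # monotone in the threshold: raising it never un-flags (thresholds
    # capped below the column maximum, past which all-noise is an error)
    for (thr in c(0.1, 0.3, 0.5, 0.7)) {
        lo <- remove_noise(model, p, threshold = thr)
        for (thr2 in seq(thr, 0.75, by = 0.1)) {
            hi <- remove_noise(model, p, threshold = thr2)
            expect_true(all(hi$noise >= lo$noise))
        }
    }
    expect_error(remove_noise(model, p, threshold = 0.95), "no resolvable")

    # slowest non-noise cluster is reported
    out <- remove_noise(model, cbind(c(0.8, 0.7), c(0.39, 0.2),
                                     c(0.3, 0.1)))
    slow <- slowest_tau(out)
    expect_equal(slow$cluster, 1L)
    expect_equal(slow$tau, 0.1)
})

test_that("postprocessing is invariant to within-sample label permutation", {
    fit <- shared_fit()
    chain <- fit$chain
    perm <- permute_chain_labels(chain, seed = 77)
    m1 <- correct_labels(chain)
    m2 <- correct_labels(perm)
    expect_equal(m2$K_prime, m1$K_prime)
    expect_equal(m2$map_lambda, m1$map_lambda)
    expect_equal(m2$map_tau, m1$map_tau)
    expect_equal(m2$ci_tau, m1$ci_tau)
    p1 <- membership_matrix(chain, m1)
    p2 <- membership_matrix(perm, m2)
    expect_equal(unclass(p2), unclass(p1), ignore_attr = TRUE)
    n1 <- remove_noise(m1, p1)
    n2 <- remove_noise(m2, p2)
    expect_equal(n2$noise, n1$noise)
})

test_that("fingerprints report the slowest cluster and flag outliers", {
    mk_fit <- function(tau, ci, noise = FALSE, omega = 50L) {
        structure(list(tau = tau, tau_ci = ci,
                       model = list(noise = noise),
                       chain = list(Omega = omega)),
                  class = "resmix")
    }
    # slowest of (0.2, 1.2, 300) wins
    f <- mk_fit(300, c(250, 420))
    fp <- fingerprint(list(R1 = f))
    expect_equal(fp$tau_ns, 300)
    expect_false(fp$flagged)  # single residue: tau >= 4 * tau never holds

    fits <- Map(mk_fit, tau = c(1, 1, 1, 1, 10),
                ci = replicate(5, c(0.5, 12), simplify = FALSE))
    names(fits) <- paste0("R", 1:5)
    fp <- fingerprint(fits)
    expect_equal(mean(fp$tau_ns), 2.8)
    expect_false(any(fp$flagged))  # threshold 11.2 exceeds max tau 10
})

test_that("fingerprint differences propagate interval bounds", {
    a <- data.frame(residue_id = c("W1", "W2"), tau_ns = c(300, 100),
                    ci_lo = c(250, 80), ci_hi = c(420, 150),
                    n_clusters = 2L, omega = 10L, flagged = FALSE)
    b <- data.frame(residue_id = c("W1", "W3"), tau_ns = c(100, 5),
                    ci_lo = c(80, 4), ci_hi = c(150, 6),
                    n_clusters = 2L, omega = 10L, flagged = FALSE)
    d <- fingerprint_diff(a, b, data.frame(residue_a = "W1",
                                           residue_b = "W1"))
    expect_equal(d$dtau_ns, 200)
    expect_equal(d$ci_lo, 250 - 150)
    expect_equal(d$ci_hi, 420 - 80)
    expect_setequal(attr(d, "unpaired"), c("W2", "W3"))

    # identical tables, identity pairing: all zeros
    d0 <- fingerprint_diff(a, a)
    expect_true(all(d0$dtau_ns == 0))
    expect_error(fingerprint_diff(a, b,
        data.frame(residue_a = c("W1", "W1"), residue_b = c("W1", "W3"))),
        "one-to-one")
})
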