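#' Fit a Bayesian hyperexponential mixture to binding residence times
#'
#' The main entry point: infers how many exponential kinetic components the
#' observed residence times support, together with their weights, rates,
#' and residence times (with 95% credible intervals), and the posterior
#' probability of every binding event to belong to each component.
#'
#' The model is the hyperexponential mixture
#' \eqn{p(t \mid \pi, \lambda) = \sum_k \pi_k \lambda_k e^{-\lambda_k t}}
#' with conjugate `Dirichlet(gamma)` / `Gamma(alpha, beta)` priors and a
#' latent per-event indicator; a Gibbs sampler ([run_gibbs()]) draws from
#' the joint posterior, after which weight filtering, label-switching
#' correction ([correct_labels()]), and noise-cluster removal
#' ([remove_noise()]) produce `K'` interpretable kinetic clusters. With the
#' default `gamma = 1/K` the finite mixture approximates a Dirichlet
#' process, so the number of supported components is inferred, not chosen.
#'
#' @param t positive residence times (ns), a [residence_series()], or an
#'   event table with a `duration_ns` column.
#' @param K maximum number of mixture components.
#' @param n_iter,burn_in,thin Gibbs schedule (defaults give 1000 kept
#'   samples; see [gibbs_config()]).
#' @param alpha,beta,gamma prior hyperparameters ([hyperparameters()]).
#' @param seed integer RNG seed; the fit is deterministic given `(t, seed)`.
#' @param weight_numerator weight-filter numerator ([filter_weights()]).
#' @param noise_threshold membership threshold for noise flagging
#'   ([remove_noise()]).
#' @param store_z keep per-sample indicators (needed for kinetic mapping).
#' @param verbose print sampler progress.
#'
#' @return object of class `"resmix"`: list with the input `t`, the
#'   `"gibbs_chain"` `chain`, the `"cluster_model"` `model`, the
#'   `membership` matrix, `tau`/`tau_ci` of the slowest non-noise cluster,
#'   and the matched `call`. Methods: [print()], [summary()], [coef()],
#'   [plot()], [predict()], [simulate()], [residuals()], [logLik()].
#'
#' @examples
#' set.seed(42)
#' t <- rhypexp(2000, weights = c(0.8, 0.2), rates = c(5, 0.1))
#' fit <- resmix(t, K = 10, n_iter = 4000, burn_in = 1000, thin = 10,
#'               seed = 1)
#' summary(fit)
#' coef(fit)
#' @export
resmix <- function(t, K = 15, n_iter = 110000, burn_in = 10000, thin = 100,
                   alpha = 1, beta = 3, gamma = 1 / K, seed = 1L,
                   weight_numerator = 10, noise_threshold = 0.4,
                   store_z = TRUE, verbose = FALSE) {
    if (is.data.frame(t)) {
        if (!"duration_ns" %in% names(t))
            stop("event table must have a 'duration_ns' column")
        t <- t$duration_ns
    }
    if (inherits(t, "residence_series")) t <- t$durations

    config <- gibbs_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
                           seed = seed, K = K, alpha = alpha, beta = beta,
                           gamma = gamma)
    chain <- run_gibbs(t, config, store_z = store_z, verbose = verbose)
    model <- correct_labels(chain, numerator = weight_numerator)
    membership <- if (store_z) membership_matrix(chain, model) else NULL
    if (!is.null(membership))
        model <- remove_noise(model, membership, threshold = noise_threshold)
    slow <- slowest_tau(model)

    fit <- list(t = t, chain = chain, model = model,
                membership = membership,
                tau = slow$tau, tau_ci = slow$ci,
                slowest_cluster = slow$cluster,
                call = match.call())
    class(fit) <- "resmix"
    fit
}

#' @export
print.resmix <- function(x, ...) {
    m <- x$model
    cat("Bayesian residence-time mixture fit\n")
    cat("  events:", x$chain$Omega,
        "| kept samples:", x$chain$w,
        "| K' =", m$K_prime, "clusters,",
        sum(!m$noise), "signal\n")
    cat("  slowest residence time tau =", format(x$tau, digits = 3),
        "ns  (95% CI ", format(x$tau_ci[1], digits = 3), "-",
        format(x$tau_ci[2], digits = 3), " ns)\n", sep = "")
    invisible(x)
}

#' @export
summary.resmix <- function(object, ...) {
    m <- object$model
    tab <- data.frame(cluster = seq_len(m$K_prime),
                      weight = m$map_weight,
                      rate_ns = m$map_lambda,
                      rate_lo = m$ci_lambda[, 1L],
                      rate_hi = m$ci_lambda[, 2L],
                      tau_ns = m$map_tau,
                      tau_lo = m$ci_tau[, 1L],
                      tau_hi = m$ci_tau[, 2L],
                      multimodal = m$multimodal,
                      noise = m$noise)
    out <- list(table = tab, Omega = object$chain$Omega,
                w = object$chain$w, K = object$chain$config$hp$K,
                tau = object$tau, tau_ci = object$tau_ci,
                call = object$call)
    class(out) <- "summary.resmix"
    out
}

#' @export
print.summary.resmix <- function(x, ...) {
    cat("Bayesian residence-time mixture fit\n")
    cat("Call: ", deparse(x$call), "\n\n")
    cat("Events:", x$Omega, " Kept posterior samples:", x$w,
        " Component bound K:", x$K, "\n\n")
    cat("Kinetic clusters (MAP estimates, 95% credible intervals):\n")
    tab <- x$table
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 3)
    print(tab, row.names = FALSE)
    cat("\nSlowest process: tau =", format(x$tau, digits = 3),
        "ns (95% CI", format(x$tau_ci[1], digits = 3), "-",
        format(x$tau_ci[2], digits = 3), "ns)\n")
    invisible(x)
}

#' @export
coef.resmix <- function(object, all = FALSE, ...) {
    m <- object$model
    keep <- if (all) seq_len(m$K_prime) else which(!m$noise)
    cbind(weight = m$map_weight[keep],
          rate = m$map_lambda[keep],
          tau = m$map_tau[keep])
}

#' @export
logLik.resmix <- function(object, ...) {
    m <- object$model
    keep <- !m$noise
    wts <- m$map_weight[keep] / sum(m$map_weight[keep])
    ll <- sum(log(dhypexp(object$t, wts, m$map_lambda[keep])))
    structure(ll, df = 2 * sum(keep) - 1, nobs = length(object$t),
              class = "logLik")
}

#' Simulate residence times from a fitted mixture
#'
#' Draws from the hyperexponential distribution at the MAP parameters of
#' the non-noise clusters (weights renormalized).
#'
#' @param object a `"resmix"` fit.
#' @param nsim number of draws per simulation.
#' @param seed optional seed.
#' @param ... unused.
#' @return numeric vector of simulated durations (ns).
#' @export
simulate.resmix <- function(object, nsim = 1, seed = NULL, ...) {
    m <- object$model
    keep <- !m$noise
    wts <- m$map_weight[keep] / sum(m$map_weight[keep])
    draw <- function() rhypexp(nsim, wts, m$map_lambda[keep])
    if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Cluster predictions for the observed binding events
#'
#' `type = "membership"` returns the per-event posterior membership matrix;
#' `type = "cluster"` returns the hard assignment (argmax cluster per
#' event, ties broken toward the slower cluster, `NA` when no sample
#' assigns the event to any surviving component).
#'
#' @param object a `"resmix"` fit with stored indicators.
#' @param type `"membership"` or `"cluster"`.
#' @param ... unused.
#' @export
predict.resmix <- function(object, type = c("membership", "cluster"), ...) {
    type <- match.arg(type)
    p <- object$membership
    if (is.null(p)) stop("fit lacks a membership matrix (store_z = FALSE)")
    if (type == "membership") return(p)
    argmax_slow(p)
}

# argmax over clusters, ties toward the slower cluster (higher index,
# clusters being ordered fastest to slowest); all-zero rows give NA
argmax_slow <- function(p) {
    apply(p, 1L, function(row) {
        if (all(row == 0)) return(NA_integer_)
        idx <- which(row == max(row))
        idx[length(idx)]
    })
}

#' Cox-Snell residuals of a fitted residence-time mixture
#'
#' For a correctly specified model the transformed residuals
#' \eqn{e_n = -\log S(t_n)} (with `S` the fitted mixture survival at the
#' MAP parameters) are distributed as `Exp(1)`; a QQ plot against
#' exponential quantiles is a goodness-of-fit check.
#'
#' @param object a `"resmix"` fit.
#' @param ... unused.
#' @export
residuals.resmix <- function(object, ...) {
    m <- object$model
    keep <- !m$noise
    wts <- m$map_weight[keep] / sum(m$map_weight[keep])
    -log(phypexp(object$t, wts, m$map_lambda[keep], lower.tail = FALSE))
}

#' Plot a fitted residence-time mixture
#'
#' `type = "survival"`: the empirical survival function on semi-log axes
#' with the fitted mixture survival and its per-cluster components
#' overlaid; the slowest component should track the long-event tail.
#' `type = "clusters"`: the posterior samples in `(log10 rate, log10
#' weight)` space colored by cluster, the view in which label-switching
#' correction operates.
#'
#' @param x a `"resmix"` fit.
#' @param type plot kind.
#' @param ... passed to the base plotting functions.
#' @export
plot.resmix <- function(x, type = c("survival", "clusters"), ...) {
    type <- match.arg(type)
    m <- x$model
    if (type == "survival") {
        sf <- survival_function(x$t)
        keep <- which(!m$noise)
        wts <- m$map_weight[keep] / sum(m$map_weight[keep])
        graphics::plot(sf$time, sf$surv, log = "y", type = "s",
                       xlab = "residence time t (ns)", ylab = "S(t)",
                       main = "Residence-time survival", ...)
        tt <- seq(min(sf$time), max(sf$time), length.out = 400)
        graphics::lines(tt, phypexp(tt, wts, m$map_lambda[keep],
                                    lower.tail = FALSE),
                        col = "red", lwd = 2)
        for (i in seq_along(keep))
            graphics::lines(tt, wts[i] * exp(-m$map_lambda[keep[i]] * tt),
                            col = "steelblue", lty = 2)
        graphics::legend("topright", bty = "n",
                         legend = c("empirical", "mixture", "components"),
                         col = c("black", "red", "steelblue"),
                         lty = c(1, 1, 2))
    } else {
        lam <- unlist(lapply(m$clusters, `[[`, "lambda"))
        wts <- unlist(lapply(m$clusters, `[[`, "pi"))
        cl <- rep(seq_len(m$K_prime),
                  vapply(m$clusters, function(cc) length(cc$lambda),
                         integer(1)))
        graphics::plot(log10(lam), log10(wts), col = cl, pch = 20,
                       xlab = "log10 rate (1/ns)", ylab = "log10 weight",
                       main = "Posterior samples by kinetic cluster", ...)
        graphics::legend("bottomleft", bty = "n", pch = 20,
                         col = seq_len(m$K_prime),
                         legend = paste0("cluster ", seq_len(m$K_prime),
                                         ifelse(m$noise, " (noise)", "")))
    }
    invisible(x)
}
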