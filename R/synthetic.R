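#' Ground-truth synthetic residence-time data
#'
#' Generates waiting times from a known hyperexponential mixture for
#' validating the full inference pipeline: a component is chosen with
#' probability `pi_k`, then a duration drawn from `Exp(lambda_k)`. The
#' default scenario is the three-component validation mixture
#' `pi = (0.9, 0.09, 0.01)`, `lambda = (5, 0.5, 0.05)` ns^-1 with
#' `n = 5e4` draws: components separated by roughly an order of magnitude,
#' with the slow, rare component carrying ~1% of events. The returned
#' labels exist only for checking recovery against ground truth; they must
#' never be passed to the inference.
#'
#' Named alternative scenarios are provided for power exploration:
#' `"two_component"` (`pi = (0.8, 0.2)`, `lambda = (5, 0.1)`),
#' `"four_component"` (`pi = (0.6, 0.25, 0.1, 0.05)`,
#' `lambda = (10, 1, 0.1, 0.01)`), and `"close_rates"`
#' (`pi = (0.7, 0.3)`, `lambda = (1, 0.3)`, rates only ~3x apart).
#'
#' @param n number of events.
#' @param weights,rates ground-truth mixture parameters.
#' @param seed integer seed; draws are bit-identical given the seed.
#' @param scenario optional named scenario overriding `weights`/`rates`.
#' @return list with `durations`, `labels`, `weights`, `rates`, `n`,
#'   `seed`.
#' @export
synthetic_dataset <- function(n = 5e4, weights = c(0.9, 0.09, 0.01),
                              rates = c(5, 0.5, 0.05), seed = 1L,
                              scenario = NULL) {
    if (!is.null(scenario)) {
        sc <- switch(match.arg(scenario, c("validation", "two_component",
                                           "four_component", "close_rates")),
            validation = list(w = c(0.9, 0.09, 0.01), r = c(5, 0.5, 0.05)),
            two_component = list(w = c(0.8, 0.2), r = c(5, 0.1)),
            four_component = list(w = c(0.6, 0.25, 0.1, 0.05),
                                  r = c(10, 1, 0.1, 0.01)),
            close_rates = list(w = c(0.7, 0.3), r = c(1, 0.3)))
        weights <- sc$w
        rates <- sc$r
    }
    draw <- with_local_seed(seed, rhypexp(n, weights, rates, labels = TRUE))
    list(durations = draw$durations, labels = draw$labels,
         weights = weights, rates = rates, n = n, seed = seed)
}

#' Toy distance series with a known contact pattern
#'
#' Builds a per-frame minimum-distance series whose in/out-of-contact
#' pattern is specified exactly, so that [extract_events()] must recover
#' it: in-contact runs are placed `margin` below the cutoff and
#' out-of-contact runs `margin` above, with uniform jitter strictly
#' smaller than the margin so no frame can cross the cutoff.
#'
#' @param pattern data frame with columns `state` (`"in"`/`"out"`) and
#'   `length` (run lengths in frames), or a list of `c(state, length)`
#'   pairs.
#' @param cutoff contact cutoff (Angstrom).
#' @param margin distance of the run levels from the cutoff (Angstrom).
#' @param jitter half-width of uniform jitter; must be `< margin`.
#' @param seed optional seed for the jitter.
#' @return numeric distance vector (Angstrom), one value per frame, with
#'   the generating pattern attached as attribute `"pattern"`.
#' @export
make_toy_distance_series <- function(pattern, cutoff = 7, margin = 1,
                                     jitter = 0.5, seed = NULL) {
    if (!is.data.frame(pattern))
        pattern <- data.frame(
            state = vapply(pattern, function(p) as.character(p[1L]),
                           character(1)),
            length = vapply(pattern, function(p) as.numeric(p[2L]),
                            numeric(1)))
    stopifnot(all(pattern$state %in% c("in", "out")),
              all(pattern$length >= 1))
    if (jitter >= margin)
        stop("'jitter' must be smaller than 'margin' or frames could ",
             "cross the cutoff")
    level <- ifelse(pattern$state == "in", cutoff - margin, cutoff + margin)
    base <- rep(level, pattern$length)
    jit <- if (jitter > 0) {
        gen <- function() runif(length(base), -jitter, jitter)
        if (is.null(seed)) gen() else with_local_seed(seed, gen())
    } else 0
    structure(base + jit, pattern = pattern)
}
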