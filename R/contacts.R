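#' Extract binding events from a per-frame minimum-distance series
#'
#' Applies the single-cutoff contact definition: a residue-ligand contact
#' exists at frame `n` if the minimum distance between any particle of the
#' residue and any particle of the ligand is at most `cutoff`. Each maximal
#' contiguous run of in-contact frames becomes exactly one binding event
#' with start frame \eqn{s_n} (0-based) and duration \eqn{t_n} = run length
#' x `frame_interval`. A ligand that leaves and re-enters produces separate
#' events (no hysteresis or gap tolerance). An event still in contact at
#' the final frame is emitted with its observed duration and flagged
#' `censored`.
#'
#' A single in-cutoff frame yields duration `frame_interval`, not zero:
#' zero durations would break the exponential likelihood downstream.
#'
#' @param distances numeric vector of per-frame minimum distances (Angstrom).
#' @param cutoff contact cutoff (Angstrom); default 7.
#' @param frame_interval time per frame (ns); default 1.
#' @param residue_id,ligand_id integer labels carried into the event table.
#' @return data frame with columns `residue_id`, `ligand_id`, `start_frame`,
#'   `duration_ns`, `censored` (one row per event; zero rows if the ligand
#'   never comes within the cutoff).
#' @seealso [survival_function()], [make_toy_distance_series()]
#' @export
extract_events <- function(distances, cutoff = 7, frame_interval = 1,
                           residue_id = NA_integer_, ligand_id = NA_integer_) {
    if (length(distances) == 0L) stop("empty distance series")
    bad <- which(!is.finite(distances))
    if (length(bad))
        stop("non-finite distance at frame ", bad[1L] - 1L)
    if (cutoff <= 0) stop("'cutoff' must be positive")
    if (frame_interval <= 0) stop("'frame_interval' must be positive")

    r <- rle(distances <= cutoff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths           # 0-based start frames
    keep <- r$values
    n_frames <- length(distances)
    m <- sum(keep)
    data.frame(residue_id = rep(residue_id, m),
               ligand_id = rep(ligand_id, m),
               start_frame = starts[keep],
               duration_ns = r$lengths[keep] * frame_interval,
               censored = ends[keep] == n_frames)
}

#' Residence-time series for one residue
#'
#' A light container for the \eqn{\Omega} observed residence times
#' \eqn{t = (t_1, \ldots, t_\Omega)} of one residue, the data vector of the
#' mixture model.
#'
#' @param durations positive residence times (ns).
#' @param residue_id residue label (integer, or `"all"` for pooled series).
#' @param events optional event table the durations came from.
#' @return object of class `"residence_series"`.
#' @export
residence_series <- function(durations, residue_id = NA_integer_,
                             events = NULL) {
    durations <- as.numeric(durations)
    if (length(durations) < 1L) stop("at least one residence time required")
    if (any(!is.finite(durations)) || any(durations <= 0))
        stop("residence times must be finite and positive")
    structure(list(residue_id = residue_id, durations = durations,
                   Omega = length(durations), events = events),
              class = "residence_series")
}

#' @export
print.residence_series <- function(x, ...) {
    cat("Residence-time series: residue", x$residue_id,
        "with", x$Omega, "events,",
        "median", format(median(x$durations), digits = 3), "ns\n")
    invisible(x)
}

#' Split an event table into per-residue residence series
#'
#' @param events event table as produced by [extract_events()] or
#'   [read_events()].
#' @return named list of [residence_series()] objects, one per residue.
#' @export
events_to_series <- function(events) {
    stopifnot(is.data.frame(events),
              all(c("residue_id", "duration_ns") %in% names(events)))
    lapply(split(events, events$residue_id), function(df)
        residence_series(df$duration_ns, residue_id = df$residue_id[1L],
                         events = df))
}

#' Pool residence series across residues
#'
#' Concatenates the residence times of several residues into one series
#' (residue label `"all"`), e.g. for a whole-protein survival function
#' computed from the combined set of contact times.
#'
#' @param series_list non-empty list of [residence_series()] objects.
#' @return a pooled [residence_series()].
#' @export
pool_series <- function(series_list) {
    if (length(series_list) == 0L) stop("no series to pool")
    stopifnot(all(vapply(series_list, inherits, logical(1),
                         "residence_series")))
    residence_series(unlist(lapply(series_list, `[[`, "durations"),
                            use.names = FALSE),
                     residue_id = "all")
}

#' Empirical survival function of residence times
#'
#' \eqn{S(t)} = fraction of events with duration at least `t`, evaluated at
#' the sorted unique durations. `S` starts at exactly 1 and is
#' non-increasing; on semi-log axes a single-exponential process appears as
#' a straight line of slope \eqn{-\lambda}.
#'
#' @param t positive residence times (ns), or a [residence_series()].
#' @return data frame with columns `time` and `surv`.
#' @export
survival_function <- function(t) {
    if (inherits(t, "residence_series")) t <- t$durations
    if (length(t) == 0L) stop("empty residence-time vector")
    if (any(t <= 0)) stop("residence times must be positive")
    times <- sort(unique(t))
    n <- length(t)
    counts <- tabulate(match(t, times), length(times))
    below <- cumsum(counts) - counts       # events strictly shorter than times[i]
    data.frame(time = times, surv = 1 - below / n)
}

#' Read or write a binding-event table
#'
#' Delimited-text event tables with header columns `residue_id`,
#' `ligand_id`, `start_frame`, `duration_ns`, `censored`.
#'
#' @param path file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return `read_events()` returns the event data frame.
#' @export
read_events <- function(path, sep = ",") {
    df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
    need <- c("residue_id", "ligand_id", "start_frame", "duration_ns",
              "censored")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("event table ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
    df$censored <- as.logical(df$censored)
    df
}

#' @rdname read_events
#' @param events event data frame.
#' @export
write_events <- function(events, path, sep = ",") {
    write.table(events, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}
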