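#' Map binding events (and their trajectory frames) to kinetic clusters
#'
#' Each event `n` covers the trajectory segment from `start_frame` to
#' `start_frame + duration/frame_interval`; the segment is assigned to the
#' cluster with the highest membership probability `p[n, k']`, clustering
#' the trajectory by binding timescale. Ties are broken toward the slower
#' cluster (conservative for identifying long-lived poses); events whose
#' membership row is all zero are left unassigned (`NA`).
#'
#' @param events event table (rows aligned with `memberships`).
#' @param memberships `Omega x K'` matrix from [membership_matrix()].
#' @param frame_interval time per frame (ns).
#' @return data frame with `event`, `residue_id`, `ligand_id`,
#'   `start_frame`, `end_frame`, `cluster`, and the probability columns.
#' @export
assign_frames <- function(events, memberships, frame_interval = 1) {
    stopifnot(is.data.frame(events), nrow(events) == nrow(memberships))
    cl <- argmax_slow(memberships)
    out <- data.frame(event = seq_len(nrow(events)),
                      residue_id = events$residue_id,
                      ligand_id = events$ligand_id,
                      start_frame = events$start_frame,
                      end_frame = events$start_frame +
                          round(events$duration_ns / frame_interval),
                      cluster = cl)
    cbind(out, as.data.frame(unclass(memberships)))
}

#' Frames with the highest membership probability for a cluster
#'
#' Expands event-level assignments to frames and returns the `n` frame
#' indices whose events have the highest membership probability for
#' `cluster` (e.g. to extract representative bound poses). Ties are kept
#' in frame order.
#'
#' @param assignments output of [assign_frames()].
#' @param cluster cluster index.
#' @param n number of frames to return.
#' @return integer vector of frame indices, highest probability first.
#' @export
top_frames <- function(assignments, cluster, n) {
    pcol <- assignments[[paste0("cluster_", cluster)]]
    if (is.null(pcol)) stop("no membership column for cluster ", cluster)
    frames <- unlist(lapply(seq_len(nrow(assignments)), function(i)
        seq(assignments$start_frame[i], assignments$end_frame[i] - 1L)))
    probs <- rep(pcol, assignments$end_frame - assignments$start_frame)
    ord <- order(probs, frames, decreasing = c(TRUE, FALSE),
                 method = "radix")
    frames[ord][seq_len(min(n, length(frames)))]
}

#' Probability-weighted spatial density of the bound ligand
#'
#' Histograms ligand particle positions on a regular 3D grid, each frame's
#' contribution weighted by the probability `p[n, k']` that its binding
#' event `n` belongs to cluster `k'`. Ligand identity is erased across
#' events: molecules of the same chemical identity are treated as
#' indistinguishable. The grid covers the bounding box of the contributing
#' coordinates padded by `padding`, with the origin snapped to the spacing
#' lattice so outputs are reproducible; voxels are half-open
#' `[edge, edge + spacing)`.
#'
#' The stored `counts` array holds raw probability-weighted counts (used
#' by the voxelwise conservation identity: per-cluster counts plus
#' unassigned mass sum to the unweighted histogram). The `density` array
#' divides by (sum of frame weights x voxel volume), i.e. a per-frame
#' average number density.
#'
#' @param coords data frame with columns `frame`, `x`, `y`, `z`
#'   (Angstrom), one row per ligand particle per bound frame.
#' @param frame_events two-column data frame (`frame`, `event`) mapping
#'   each trajectory frame to the binding event covering it.
#' @param memberships membership matrix ([membership_matrix()]), or a
#'   single-column matrix of per-event weights.
#' @param cluster cluster index `k'` whose density is computed.
#' @param spacing grid spacing (Angstrom) in all directions; default 1.
#' @param padding bounding-box padding (Angstrom).
#' @return object of class `"weighted_density"`: list with 3D arrays
#'   `counts` and `density`, `origin`, `spacing`, `dims`, `cluster`,
#'   `total_weight`.
#' @export
weighted_density <- function(coords, frame_events, memberships, cluster,
                             spacing = 1, padding = 2) {
    stopifnot(all(c("frame", "x", "y", "z") %in% names(coords)),
              all(c("frame", "event") %in% names(frame_events)))
    if (spacing <= 0) stop("'spacing' must be positive")
    xyz <- as.matrix(coords[c("x", "y", "z")])
    if (any(!is.finite(xyz))) stop("non-finite coordinates")

    ev <- frame_events$event[match(coords$frame, frame_events$frame)]
    if (anyNA(ev)) stop("coordinate frame(s) missing from 'frame_events'")
    w_row <- memberships[cbind(ev, cluster)]
    if (all(w_row <= 0)) stop("no frames with positive weight for cluster ",
                              cluster)

    lo <- apply(xyz, 2L, min) - padding
    origin <- spacing * floor(lo / spacing)
    dims <- pmax(1L, ceiling((apply(xyz, 2L, max) + padding - origin) /
                                 spacing))
    idx <- floor(sweep(xyz, 2L, origin) / spacing) + 1L
    lin <- idx[, 1L] + dims[1L] * (idx[, 2L] - 1L) +
        dims[1L] * dims[2L] * (idx[, 3L] - 1L)
    counts <- array(0, dim = dims)
    acc <- rowsum(w_row, group = lin)
    counts[as.integer(rownames(acc))] <- acc[, 1L]

    frame_w <- memberships[cbind(frame_events$event, cluster)]
    total_weight <- sum(frame_w[frame_events$frame %in% coords$frame])
    structure(list(counts = counts,
                   density = counts / (total_weight * spacing^3),
                   origin = origin, spacing = rep(spacing, 3L),
                   dims = dims, cluster = cluster,
                   total_weight = total_weight),
              class = "weighted_density")
}

#' @export
print.weighted_density <- function(x, ...) {
    cat("Weighted ligand density, cluster", x$cluster, "\n")
    cat("  grid:", paste(x$dims, collapse = " x "),
        "voxels at", x$spacing[1L], "Angstrom spacing; origin (",
        paste(signif(x$origin, 5), collapse = ", "), ")\n")
    cat("  total weighted mass:", signif(sum(x$counts), 6),
        "| total frame weight:", signif(x$total_weight, 6), "\n")
    invisible(x)
}

#' Write a density grid in OpenDX format
#'
#' The plain-text OpenDX scalar-field format understood by common
#' molecular-visualization tools (VMD, ChimeraX, PyMOL).
#'
#' @param density a `"weighted_density"` (or any list with `density`/
#'   `counts`, `origin`, `spacing`, `dims`).
#' @param path output file.
#' @param what which array to write: `"density"` or `"counts"`.
#' @export
write_dx <- function(density, path, what = c("density", "counts")) {
    what <- match.arg(what)
    arr <- density[[what]]
    d <- density$dims
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("object 1 class gridpositions counts %d %d %d",
                d[1L], d[2L], d[3L]),
        sprintf("origin %.6f %.6f %.6f",
                density$origin[1L], density$origin[2L], density$origin[3L]),
        sprintf("delta %.6f 0.000000 0.000000", density$spacing[1L]),
        sprintf("delta 0.000000 %.6f 0.000000", density$spacing[2L]),
        sprintf("delta 0.000000 0.000000 %.6f", density$spacing[3L]),
        sprintf("object 2 class gridconnections counts %d %d %d",
                d[1L], d[2L], d[3L]),
        sprintf(paste("object 3 class array type double rank 0",
                      "items %d data follows"), prod(d))), con)
    # OpenDX stores the grid with the last (z) index varying fastest
    vals <- as.vector(aperm(arr, c(3L, 2L, 1L)))
    full <- length(vals) %/% 3L * 3L
    if (full > 0L)
        writeLines(sprintf("%.10g %.10g %.10g",
                           vals[seq(1L, full, 3L)],
                           vals[seq(2L, full, 3L)],
                           vals[seq(3L, full, 3L)]), con)
    if (full < length(vals))
        writeLines(paste(sprintf("%.10g", vals[(full + 1L):length(vals)]),
                         collapse = " "), con)
    writeLines(c("attribute \"dep\" string \"positions\"",
                 "object \"density\" class field",
                 "component \"positions\" value 1",
                 "component \"connections\" value 2",
                 "component \"data\" value 3"), con)
    invisible(path)
}
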