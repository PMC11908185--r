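#' Per-residue residence-time fingerprint
#'
#' Condenses per-residue fits into one row per residue: the residence time
#' of the slowest non-noise cluster with its 95% credible interval, the
#' number of signal clusters, and the event count. Residues whose tau is
#' at least `flag_factor` times the mean tau across residues are flagged
#' as long-lived interaction sites.
#'
#' @param fits named list of `"resmix"` fits (names = residue ids), or a
#'   single fit.
#' @param flag_factor multiple of the mean tau above which a residue is
#'   flagged; default 4.
#' @return data frame with columns `residue_id`, `tau_ns`, `ci_lo`,
#'   `ci_hi`, `n_clusters`, `omega`, `flagged`.
#' @export
fingerprint <- function(fits, flag_factor = 4) {
    if (inherits(fits, "resmix")) fits <- list(fits)
    if (length(fits) == 0L) stop("no fits supplied")
    ids <- names(fits)
    if (is.null(ids)) ids <- as.character(seq_along(fits))
    rows <- lapply(seq_along(fits), function(i) {
        f <- fits[[i]]
        data.frame(residue_id = ids[i],
                   tau_ns = f$tau,
                   ci_lo = f$tau_ci[1L], ci_hi = f$tau_ci[2L],
                   n_clusters = sum(!f$model$noise),
                   omega = f$chain$Omega)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$flagged <- out$tau_ns >= flag_factor * mean(out$tau_ns)
    out
}

#' Residence-time differences between two systems
#'
#' Computes `delta tau = tau_A - tau_B` for residue pairs matched by an
#' explicit pairing (e.g. from a sequence alignment of two receptors).
#' Interval bounds propagate as the interval difference
#' `(lo_A - hi_B, hi_A - lo_B)`. Residues missing from either table or
#' the pairing are listed in the `"unpaired"` attribute, not an error.
#'
#' @param table_a,table_b fingerprint tables from [fingerprint()].
#' @param pairing two-column data frame mapping `residue_a` to
#'   `residue_b`, one-to-one; default pairs identical residue ids.
#' @return data frame with `residue_a`, `residue_b`, `dtau_ns`, `ci_lo`,
#'   `ci_hi`; attribute `"unpaired"` lists unmatched residues.
#' @export
fingerprint_diff <- function(table_a, table_b, pairing = NULL) {
    if (is.null(pairing))
        pairing <- data.frame(residue_a = table_a$residue_id,
                              residue_b = table_a$residue_id)
    names(pairing)[1:2] <- c("residue_a", "residue_b")
    if (anyDuplicated(pairing$residue_a) || anyDuplicated(pairing$residue_b))
        stop("'pairing' must map residues one-to-one")
    ia <- match(as.character(pairing$residue_a),
                as.character(table_a$residue_id))
    ib <- match(as.character(pairing$residue_b),
                as.character(table_b$residue_id))
    ok <- !is.na(ia) & !is.na(ib)
    out <- data.frame(residue_a = pairing$residue_a[ok],
                      residue_b = pairing$residue_b[ok],
                      dtau_ns = table_a$tau_ns[ia[ok]] -
                          table_b$tau_ns[ib[ok]],
                      ci_lo = table_a$ci_lo[ia[ok]] - table_b$ci_hi[ib[ok]],
                      ci_hi = table_a$ci_hi[ia[ok]] - table_b$ci_lo[ib[ok]])
    unpaired <- c(setdiff(as.character(table_a$residue_id),
                          as.character(pairing$residue_a)),
                  setdiff(as.character(table_b$residue_id),
                          as.character(pairing$residue_b)),
                  as.character(pairing$residue_a[!ok]))
    attr(out, "unpaired") <- unique(unpaired)
    out
}

#' Project residence times onto a structure's B-factor column
#'
#' Writes per-residue tau values into the temperature-factor column of a
#' PDB copy so long-lived interaction sites can be colored in standard
#' viewers. Requires the `bio3d` package.
#'
#' @param fp fingerprint table from [fingerprint()].
#' @param pdb_in input PDB path.
#' @param pdb_out output PDB path.
#' @param default B-factor for residues absent from the table.
#' @export
project_tau_pdb <- function(fp, pdb_in, pdb_out, default = 0) {
    if (!requireNamespace("bio3d", quietly = TRUE))
        stop("'bio3d' is required for structure projection")
    pdb <- bio3d::read.pdb(pdb_in)
    tau <- setNames(fp$tau_ns, as.character(fp$residue_id))
    b <- tau[as.character(pdb$atom$resno)]
    pdb$atom$b <- ifelse(is.na(b), default, b)
    bio3d::write.pdb(pdb, file = pdb_out)
    invisible(pdb_out)
}
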