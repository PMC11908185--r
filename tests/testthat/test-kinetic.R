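events_df <- function(starts, durs, res = 1L, lig = 1L) {
    data.frame(residue_id = res, ligand_id = lig, start_frame = starts,
               duration_ns = durs, censored = FALSE)
}

test_that("events map to their argmax cluster, ties toward the slower", {
    ev <- events_df(c(0, 10, 20), c(5, 5, 5))
    p <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(0, 0))
    colnames(p) <- paste0("cluster_", 1:2)
    fa <- assign_frames(ev, p)
    expect_equal(fa$cluster, c(1L, 2L, NA))       # tie -> slower cluster 2
    expect_equal(fa$end_frame, c(5, 15, 25))
    # frames never extend beyond [s_n, s_n + t_n]
    expect_true(all(fa$end_frame - fa$start_frame == 5))
})

test_that("highest-probability frames match a sort-and-take oracle", {
    set.seed(55)
    n_ev <- 25
    ev <- events_df(seq(0, by = 4, length.out = n_ev), rep(4, n_ev))
    p1 <- runif(n_ev)
    p <- cbind(p1, 1 - p1)
    colnames(p) <- paste0("cluster_", 1:2)
    fa <- assign_frames(ev, p)
    got <- top_frames(fa, cluster = 1, n = 50)
    # oracle: every frame inherits its event's probability; sort descending
    frames <- 0:(4 * n_ev - 1)
    probs <- rep(p1, each = 4)
    oracle <- frames[order(-probs, frames)][1:50]
    expect_equal(got, oracle)
})

test_that("weighted densities accumulate like the naive per-frame loop", {
    # one frame, one particle, weight 0.5
    coords <- data.frame(frame = 0, x = 1.2, y = 3.4, z = -0.7)
    fe <- data.frame(frame = 0, event = 1)
    p <- matrix(c(0.5, 0.5), 1, 2)
    d <- weighted_density(coords, fe, p, cluster = 1, spacing = 1)
    expect_equal(sum(d$counts), 0.5)
    expect_equal(sum(d$counts > 0), 1)

    # random toy system vs explicit loop
    set.seed(56)
    n_frames <- 100
    coords <- data.frame(frame = rep(0:(n_frames - 1), each = 3),
                         x = runif(300, -5, 5), y = runif(300, -5, 5),
                         z = runif(300, -5, 5))
    fe <- data.frame(frame = 0:(n_frames - 1),
                     event = sample.int(10, n_frames, replace = TRUE))
    p <- matrix(runif(20), 10, 2)
    d <- weighted_density(coords, fe, p, cluster = 2, spacing = 1,
                          padding = 2)
    oracle <- array(0, dim = d$dims)
    for (r in seq_len(nrow(coords))) {
        w <- p[fe$event[match(coords$frame[r], fe$frame)], 2]
        ijk <- floor((c(coords$x[r], coords$y[r], coords$z[r]) - d$origin) /
                         d$spacing) + 1
        oracle[ijk[1], ijk[2], ijk[3]] <- oracle[ijk[1], ijk[2], ijk[3]] + w
    }
    expect_equal(d$counts, oracle)
    # origin snapped to the spacing lattice
    expect_equal(d$origin, round(d$origin))
    expect_error(weighted_density(coords, fe, matrix(0, 10, 2), 2),
                 "positive weight")
})

test_that("per-cluster densities and unassigned mass conserve the histogram", {
    set.seed(57)
    n_frames <- 100
    coords <- data.frame(frame = rep(0:(n_frames - 1), each = 2),
                         x = rnorm(200), y = rnorm(200), z = rnorm(200))
    fe <- data.frame(frame = 0:(n_frames - 1),
                     event = sample.int(8, n_frames, replace = TRUE))
    p <- matrix(runif(16), 8, 2)
    p <- p / (rowSums(p) + runif(8, 0, 0.5))     # rows sum to < 1
    full <- cbind(p, 1 - rowSums(p))             # unassigned as 3rd column
    parts <- lapply(1:3, function(k)
        weighted_density(coords, fe, full, cluster = k, spacing = 1)$counts)
    unweighted <- weighted_density(coords, fe, matrix(1, 8, 1),
                                   cluster = 1, spacing = 1)$counts
    expect_equal(Reduce(`+`, parts), unweighted, tolerance = 1e-12)
})

test_that("densities are equivariant under rigid translation", {
    set.seed(58)
    coords <- data.frame(frame = 0:19, x = runif(20), y = runif(20),
                         z = runif(20))
    fe <- data.frame(frame = 0:19, event = rep(1:4, 5))
    p <- matrix(runif(4), 4, 1)
    d1 <- weighted_density(coords, fe, p, cluster = 1, spacing = 1)
    shift <- c(13, -7, 4)   # multiples of the spacing keep voxel alignment
    coords2 <- transform(coords, x = x + shift[1], y = y + shift[2],
                         z = z + shift[3])
    d2 <- weighted_density(coords2, fe, p, cluster = 1, spacing = 1)
    expect_equal(d2$counts, d1$counts)
    expect_equal(d2$origin, d1$origin + shift)
})

test_that("OpenDX output encodes the grid in z-fastest order", {
    coords <- data.frame(frame = c(0, 0), x = c(0.5, 2.5), y = c(0.5, 0.5),
                         z = c(0.5, 0.5))
    fe <- data.frame(frame = 0, event = 1)
    d <- weighted_density(coords, fe, matrix(1, 1, 1), cluster = 1,
                          spacing = 1, padding = 1)
    path <- withr::local_tempfile(fileext = ".dx")
    write_dx(d, path, what = "counts")
    lines <- readLines(path)
    expect_match(lines[1],
                 sprintf("counts %d %d %d", d$dims[1], d$dims[2], d$dims[3]))
    expect_match(lines[2], "^origin ")
    # parse the data block back and compare against the array
    first_data <- grep("data follows", lines) + 1L
    n_items <- prod(d$dims)
    n_lines <- ceiling(n_items / 3)
    vals <- scan(text = lines[first_data:(first_data + n_lines - 1)],
                 quiet = TRUE)
    expect_equal(vals, as.vector(aperm(d$counts, c(3, 2, 1))))
    expect_equal(sum(vals), 2)
})
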