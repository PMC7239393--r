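#' Simulate a per-window depth track for one sample
#'
#' Window read depth is drawn from a Poisson with mean
#' `coverage * (local copy total / sex baseline)`, where the local copy
#' total sums, over the sample's Z chromosomes, 1 outside the CNV, the
#' outer copy count inside the outer-but-not-inner segment, and the inner
#' copy count inside the inner segment. A window's copy state is taken at
#' its midpoint. With `noise = FALSE` the expectation itself is returned,
#' giving an exact step profile at the breakpoints.
#'
#' @param truth A `cnv_truth` for the sample.
#' @param config A `sim_config`.
#' @param sample Sample id attached to the track.
#' @param noise Draw Poisson noise (default) or return expectations.
#' @param seed Optional seed (`set.seed` before drawing).
#' @return A `depth_track`.
#' @export
simulate_depth <- function(truth, config, sample = "sim", noise = TRUE,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  win <- config$window
  nwin <- ceiling(config$scaffold_length / win)
  start <- (seq_len(nwin) - 1L) * win + 1L
  end <- pmin(seq_len(nwin) * win, config$scaffold_length)
  mid <- (start + end) / 2
  copies <- local_copy_total(truth, mid)
  mu <- config$coverage * copies / truth_baseline(truth)
  d <- if (noise) stats::rpois(nwin, mu) else mu
  depth_track(config$scaffold, start, end, d, sample, win)
}

# per-chromosome copy count at a single position
chrom_local_copies <- function(truth, pos) {
  vapply(seq_along(truth$outer_copies), function(chr) {
    if (pos >= truth$inner$start && pos <= truth$inner$end)
      truth$inner_copies[chr]
    else if (pos >= truth$outer$start && pos <= truth$outer$end)
      truth$outer_copies[chr]
    else 1L
  }, integer(1))
}

# total copy count across chromosomes at positions `pos`
local_copy_total <- function(truth, pos) {
  n <- length(pos)
  tot <- numeric(n)
  for (chr in seq_along(truth$outer_copies)) {
    cp <- rep(1, n)
    in_out <- pos >= truth$outer$start & pos <= truth$outer$end
    in_in <- pos >= truth$inner$start & pos <= truth$inner$end
    cp[in_out] <- truth$outer_copies[chr]
    cp[in_in] <- truth$inner_copies[chr]
    tot <- tot + cp
  }
  tot
}

#' Simulate soft-clip pileups at CNV junctions
#'
#' Tandem junctions leave reads clipped exactly at the breakpoint
#' positions. Clip counts are Poisson with mean
#' `coverage * novel junction copies / baseline`: the inner breakpoints
#' carry the inner-inner (2/2) junctions, `sum(inner - outer)` of them, and
#' the outer breakpoints carry the unit-unit (3/1) junctions,
#' `sum(outer - 1)`. A single-copy genome therefore produces no junction
#' piles. Background positions acquire sporadic 1-read clips at
#' `clip_bg_rate` per bp.
#'
#' @param truth A `cnv_truth`.
#' @param config A `sim_config`.
#' @param seed Optional seed.
#' @return Data frame of class `clip_piles`: `scaffold,pos,side,count`
#'   (count `>= 1`; zero-count junctions are dropped).
#' @export
simulate_clip_piles <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- truth_baseline(truth)
  inner_j <- sum(truth$inner_copies - truth$outer_copies)
  outer_j <- sum(truth$outer_copies - 1L)
  bp <- truth$breakpoints
  pos <- integer(0); side <- character(0); count <- integer(0)
  add <- function(p, s, mu) {
    k <- stats::rpois(1, mu)
    if (k >= 1L) { pos <<- c(pos, p); side <<- c(side, s); count <<- c(count, k) }
  }
  if (inner_j > 0L) {
    add(bp[["inner_left"]], "left", config$coverage * inner_j / base)
    add(bp[["inner_right"]], "right", config$coverage * inner_j / base)
  }
  if (outer_j > 0L) {
    add(bp[["outer_left"]], "left", config$coverage * outer_j / base)
    add(bp[["outer_right"]], "right", config$coverage * outer_j / base)
  }
  nbg <- stats::rbinom(1, config$scaffold_length, config$clip_bg_rate)
  if (nbg > 0L) {
    bgpos <- sample.int(config$scaffold_length, nbg, replace = TRUE)
    bgpos <- setdiff(bgpos, pos)
    pos <- c(pos, bgpos); side <- c(side, sample(c("left", "right"),
                                                 length(bgpos), replace = TRUE))
    count <- c(count, rep(1L, length(bgpos)))
  }
  o <- order(pos)
  structure(data.frame(scaffold = rep(config$scaffold, length(pos)),
                       pos = pos[o], side = side[o], count = count[o]),
            class = c("clip_piles", "data.frame"))
}
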