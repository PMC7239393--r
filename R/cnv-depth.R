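#' Normalize a depth track to a control region
#'
#' Divides every window by the median depth over the windows of a control
#' interval known not to harbor the CNV (analogous to normalizing against
#' the CNV-free start of the scaffold). After normalization the control
#' median is exactly 1, so applying the operation twice is a no-op.
#'
#' @param track A `depth_track` (raw, or already normalized, in which case
#'   the `norm` column is renormalized).
#' @param control A `genomic_interval`; must cover at least 10 windows with
#'   positive median depth.
#' @return The track with an added/updated `norm` column and attribute
#'   `control`; class `normalized_track`.
#' @export
normalize_depth <- function(track, control) {
  vals <- if (!is.null(track$norm)) track$norm else track$depth
  mid <- (track$start + track$end) / 2
  ctrl <- in_interval(control, track$scaffold, mid)
  if (sum(ctrl) < 10L) stop("control interval must overlap >= 10 windows")
  med <- stats::median(vals[ctrl])
  if (med <= 0) stop("uncovered control region")
  track$norm <- vals / med
  attr(track, "control") <- control
  class(track) <- unique(c("normalized_track", class(track)))
  track
}

#' Integer copy number over an interval
#'
#' Estimates copy number from the median normalized depth over the windows
#' of an interval. The median total copy count is
#' `round(median * baseline)`, where `baseline` is the sample's Z
#' chromosome count (1 for a hemizygous female, 2 for a male), and the
#' per-chromosome value is `total / baseline` (so a hemizygous female is
#' simply `round(median)`). The median is used for robustness to localized
#' depth spikes (e.g. a repeat element inside the region); windows
#' overlapping `exclude` intervals are dropped before the median.
#'
#' @param track A `normalized_track`.
#' @param interval A `genomic_interval` covered by at least 5 windows.
#' @param baseline Z-chromosome baseline (1 female, 2 male).
#' @param exclude Optional list of `genomic_interval` to mask out (e.g. the
#'   nested inner segment, or a repeat-spike mask).
#' @return List with `total` (integer copies summed over chromosomes),
#'   `per_chromosome`, `median_norm` and `n_windows`.
#' @export
copy_number <- function(track, interval, baseline = 1, exclude = NULL) {
  if (is.null(track$norm)) stop("track must be normalized first")
  mid <- (track$start + track$end) / 2
  keep <- in_interval(interval, track$scaffold, mid)
  if (!is.null(exclude)) {
    if (inherits(exclude, "genomic_interval")) exclude <- list(exclude)
    for (ex in exclude) keep <- keep & !in_interval(ex, track$scaffold, mid)
  }
  if (sum(keep) < 5L) stop("interval covered by fewer than 5 windows")
  med <- stats::median(track$norm[keep])
  total <- as.integer(round(med * baseline))
  list(total = total, per_chromosome = total / baseline,
       median_norm = med, n_windows = sum(keep))
}

#' Segment a normalized track into piecewise-constant levels
#'
#' Greedy binary segmentation: at each step the candidate changepoint
#' maximizes the CUSUM-weighted mean difference
#' `sqrt(k (n-k) / n) * |mean(left) - mean(right)|` (for a noiseless
#' piecewise-constant signal this maximizer sits exactly on a true
#' boundary). A split is accepted when the score exceeds a noise
#' calibration (1.5 x the robustly estimated window sd x `sqrt(2 log n)`,
#' which keeps Poisson noise on high plateaus, where the sd grows with
#' copy level, from generating spurious cuts) and the medians of the
#' `min_seg` windows flanking the cut differ by at least `step_threshold`
#' copies. Segments shorter than `min_seg`
#' windows are never created, and adjacent segments whose medians differ by
#' less than the threshold are re-merged at the end.
#'
#' @param track A `normalized_track` (or any `depth_track`; the `norm`
#'   column is preferred).
#' @param min_seg Minimum segment length in windows (default 10).
#' @param step_threshold Minimum median step between adjacent segments, in
#'   copies (default 0.5).
#' @return Data frame of class `depth_segments`: `start_win, end_win,
#'   start, end, n_windows, level` (level = median of the segment).
#' @export
segment_track <- function(track, min_seg = 10L, step_threshold = 0.5) {
  x <- if (!is.null(track$norm)) track$norm else track$depth
  n <- length(x)
  if (n < 2L * min_seg) stop("need at least 2 * min_seg windows")
  bounds <- sort(unique(c(0L, seg_split(x, 1L, n, min_seg, step_threshold), n)))
  # merge adjacent segments with sub-threshold median steps
  repeat {
    if (length(bounds) <= 2L) break
    meds <- vapply(seq_len(length(bounds) - 1L), function(j)
      stats::median(x[(bounds[j] + 1L):bounds[j + 1L]]), numeric(1))
    gaps <- abs(diff(meds))
    if (!length(gaps) || all(gaps >= step_threshold)) break
    drop <- which.min(gaps) + 1L
    bounds <- bounds[-drop]
  }
  nseg <- length(bounds) - 1L
  out <- data.frame(scaffold = track$scaffold[1],
                    start_win = bounds[-length(bounds)] + 1L,
                    end_win = bounds[-1])
  out$start <- track$start[out$start_win]
  out$end <- track$end[out$end_win]
  out$n_windows <- out$end_win - out$start_win + 1L
  out$level <- vapply(seq_len(nseg), function(j)
    stats::median(x[out$start_win[j]:out$end_win[j]]), numeric(1))
  structure(out, window = track_window(track),
            class = c("depth_segments", "data.frame"))
}

# recursive binary splitting; returns interior boundary indices (absolute,
# right-inclusive) within x[lo..hi]
seg_split <- function(x, lo, hi, min_seg, step_threshold) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg) return(integer(0))
  seg <- x[lo:hi]
  cs <- cumsum(seg)
  k <- seq.int(min_seg, n - min_seg)
  meanL <- cs[k] / k
  meanR <- (cs[n] - cs[k]) / (n - k)
  score <- sqrt(k * (n - k) / n) * abs(meanL - meanR)
  kbest <- k[which.max(score)]
  # two-part acceptance: (i) the CUSUM score must exceed what pure noise
  # produces (noise sd estimated robustly from first differences; under
  # noise the max score is ~ sigma * sqrt(2 log n)); (ii) the medians of
  # the min_seg windows flanking the cut must step by >= step_threshold
  sigma <- stats::mad(diff(seg)) / sqrt(2)
  lambda <- max(1.5 * sigma * sqrt(2 * log(n)), 1e-9)
  if (max(score) < lambda) return(integer(0))
  m <- min(min_seg, kbest, n - kbest)
  medL <- stats::median(seg[(kbest - m + 1L):kbest])
  medR <- stats::median(seg[(kbest + 1L):(kbest + m)])
  if (abs(medL - medR) < step_threshold) return(integer(0))
  cut <- lo + kbest - 1L
  c(seg_split(x, lo, cut, min_seg, step_threshold), cut,
    seg_split(x, cut + 1L, hi, min_seg, step_threshold))
}
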