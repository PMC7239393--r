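#' Detect breakpoints from soft-clip pileups
#'
#' Positions where at least `min_support` reads are clipped are putative
#' structural-variant breakpoints (automating what is otherwise done by
#' eye in a genome browser). Qualifying positions within `merge_radius` bp
#' of each other are merged, keeping the position with the highest clip
#' count.
#'
#' @param piles A `clip_piles` data frame (`scaffold,pos,side,count`).
#' @param min_support Minimum clipped reads at a position (default 3).
#' @param merge_radius Merge radius in bp (default 5).
#' @return Data frame `scaffold,pos,side,count`, sorted by position; zero
#'   rows when nothing qualifies.
#' @export
detect_breakpoints <- function(piles, min_support = 3L, merge_radius = 5L) {
  keep <- piles[piles$count >= min_support, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(data.frame(scaffold = character(0), pos = integer(0),
                      side = character(0), count = integer(0)))
  keep <- keep[order(keep$scaffold, keep$pos), , drop = FALSE]
  grp <- cumsum(c(1L, (diff(keep$pos) > merge_radius) |
                    (keep$scaffold[-1] != keep$scaffold[-nrow(keep)])))
  out <- do.call(rbind, lapply(split(keep, grp), function(g)
    g[which.max(g$count), , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Assemble a nested CNV call from depth segments and breakpoints
#'
#' Pairs the step boundaries of the segmented depth profile with the
#' nearest clip-supported breakpoints. The contiguous run of elevated
#' segments defines the outer interval and its highest plateau the nested
#' inner interval; a breakpoint within `bp_window` windows of a depth
#' boundary replaces the (window-resolution) boundary with its exact
#' position. A depth boundary with no breakpoint within `flag_window`
#' windows is flagged `"depth-only"`; an elevated region with a single
#' plateau and no outer shoulder is flagged `"inner-only"` (outer copy
#' number 1).
#'
#' @param segments A `depth_segments` from [segment_track()].
#' @param breakpoints Breakpoint data frame from [detect_breakpoints()]
#'   (may have zero rows).
#' @param baseline Z baseline of the sample (1 female, 2 male).
#' @param bp_window Windows within which a breakpoint overrides a depth
#'   boundary (default 2).
#' @param flag_window Windows beyond which a boundary is depth-only
#'   (default 10).
#' @return A `cnv_call` (list: `outer`, `inner`, `outer_cn`, `inner_cn`
#'   per chromosome, `breakpoints`, `flags`, `support`) or `NULL` when no
#'   window is elevated.
#' @export
assemble_call <- function(segments, breakpoints, baseline = 1,
                          bp_window = 2L, flag_window = 10L) {
  win <- attr(segments, "window")
  lev_cn <- round(segments$level * baseline) / baseline  # copies per chromosome
  elev <- lev_cn > 1
  if (!any(elev)) return(NULL)
  runs <- rle(elev)
  run_end <- cumsum(runs$lengths); run_start <- run_end - runs$lengths + 1L
  eruns <- which(runs$values)
  # take the elevated run containing the maximum level
  peak <- which.max(segments$level)
  r <- eruns[vapply(eruns, function(j) peak >= run_start[j] &&
                      peak <= run_end[j], logical(1))][1]
  segs <- segments[run_start[r]:run_end[r], , drop = FALSE]
  flags <- character(0)
  inner_seg <- segs[which.max(segs$level), , drop = FALSE]
  outer_start <- segs$start[1]; outer_end <- segs$end[nrow(segs)]
  if (nrow(segs) == 1L) {
    flags <- c(flags, "inner-only")
    outer_cn <- 1
  } else {
    shoulders <- segs$level[-which.max(segs$level)]
    outer_cn <- round(stats::median(rep(shoulders,
                                        segs$n_windows[-which.max(segs$level)])) *
                        baseline) / baseline
  }
  inner_cn <- round(inner_seg$level * baseline) / baseline
  want <- c(outer_left = outer_start, inner_left = inner_seg$start,
            inner_right = inner_seg$end, outer_right = outer_end)
  got <- want; support <- rep(NA_integer_, 4L); names(support) <- names(want)
  for (nm in names(want)) {
    if (nrow(breakpoints)) {
      d <- abs(breakpoints$pos - want[[nm]])
      j <- which.min(d)
      if (d[j] <= bp_window * win) {
        got[[nm]] <- breakpoints$pos[j]; support[[nm]] <- breakpoints$count[j]
        next
      }
      if (d[j] > flag_window * win) flags <- c(flags, "depth-only")
    } else flags <- c(flags, "depth-only")
  }
  flags <- unique(flags)
  scaffold <- as.character(segs$scaffold[1])
  structure(list(
    outer = genomic_interval(scaffold, got[["outer_left"]], got[["outer_right"]]),
    inner = genomic_interval(scaffold, got[["inner_left"]], got[["inner_right"]]),
    outer_cn = outer_cn, inner_cn = inner_cn, baseline = baseline,
    breakpoints = got, support = support, flags = flags),
    class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat(sprintf("cnv_call: outer %s CN %s | inner %s CN %s%s\n",
              kb_label(x$outer), format(x$outer_cn),
              kb_label(x$inner), format(x$inner_cn),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
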