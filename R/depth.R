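#' Depth track: per-window mean sequencing depth for one sample
#'
#' @param scaffold Scaffold id.
#' @param start,end Window endpoints (1-based inclusive); windows tile the
#'   scaffold without overlap.
#' @param depth Per-window mean depth (reads), `>= 0`.
#' @param sample Sample id.
#' @param window Window size in bp.
#' @return A data frame of class `depth_track` with columns
#'   `scaffold,start,end,depth` and attributes `sample`, `window`.
#' @export
depth_track <- function(scaffold, start, end, depth, sample, window) {
  stopifnot(all(depth >= 0), all(end >= start))
  if (length(start) > 1L && any(start[-1] != end[-length(end)] + 1L))
    stop("windows must tile the scaffold without gaps or overlap")
  structure(data.frame(scaffold = scaffold, start = start, end = end,
                       depth = depth),
            sample = sample, window = window,
            class = c("depth_track", "data.frame"))
}

track_sample <- function(track) attr(track, "sample")
track_window <- function(track) attr(track, "window")

#' Read a per-position depth table into per-sample depth tracks
#'
#' Input is a TSV in the style of `samtools depth` / `vcftools --geno-depth`:
#' columns `CHROM`, `POS`, then one depth column per sample. Positions are
#' aggregated into tiling windows by mean; positions absent from the file
#' are counted as depth 0 (zero-coverage positions are conventionally
#' omitted from such files). The final, possibly partial, window is averaged
#' over the positions it actually spans up to the largest observed position.
#'
#' @param path Path to the TSV (header required).
#' @param window Window size in bp (default 100).
#' @return Named list of `depth_track`, one per sample column.
#' @export
read_depth_table <- function(path, window = 100) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3L) stop("depth table needs CHROM, POS and >=1 sample column")
  scaffold <- tab[[1]]
  pos <- suppressWarnings(as.integer(tab[[2]]))
  if (anyNA(pos)) stop("non-numeric POS at row(s): ",
                       paste(which(is.na(pos)), collapse = ", "))
  if (length(unique(scaffold)) > 1L)
    stop("read_depth_table handles one scaffold per file")
  samples <- colnames(tab)[-(1:2)]
  out <- vector("list", length(samples)); names(out) <- samples
  maxpos <- max(pos)
  nwin <- ceiling(maxpos / window)
  wstart <- (seq_len(nwin) - 1L) * window + 1L
  wend <- pmin(seq_len(nwin) * window, maxpos)
  widx <- (pos - 1L) %/% window + 1L
  for (s in samples) {
    d <- suppressWarnings(as.numeric(tab[[s]]))
    if (anyNA(d)) {
      bad <- which(is.na(d))[1]
      stop(sprintf("non-numeric depth in column '%s', row %d ('%s')",
                   s, bad, tab[[s]][bad]))
    }
    sums <- vapply(seq_len(nwin), function(w) sum(d[widx == w]), numeric(1))
    out[[s]] <- depth_track(scaffold[1], wstart, wend,
                            sums / (wend - wstart + 1), s, window)
  }
  out
}

#' Write depth tracks as a per-position TSV
#'
#' Inverse of [read_depth_table()]: every window is expanded to its
#' constituent positions, each carrying the window mean, so re-reading
#' with the same window size reproduces the tracks exactly.
#'
#' @param tracks Named list of `depth_track` sharing the same windows.
#' @param path Output path.
#' @export
write_depth_table <- function(tracks, path) {
  stopifnot(length(tracks) >= 1L)
  t1 <- tracks[[1]]
  nper <- t1$end - t1$start + 1L
  df <- data.frame(CHROM = rep(t1$scaffold, nper),
                   POS = sequence(nper, from = t1$start))
  for (s in names(tracks)) df[[s]] <- rep(tracks[[s]]$depth, nper)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
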