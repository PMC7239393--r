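#' Write simulation truth as a JSON sidecar
#'
#' Serializes the per-sample copy-number truth (intervals, per-chromosome
#' outer/inner copies, breakpoints) so a test harness can compare pipeline
#' output against it without re-running the generator.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param path Output `.json` path.
#' @export
write_truth <- function(cohort, path) {
  x <- lapply(cohort$truth, function(tr) list(
    outer = c(tr$outer$start, tr$outer$end),
    inner = c(tr$inner$start, tr$inner$end),
    outer_copies = tr$outer_copies, inner_copies = tr$inner_copies,
    breakpoints = as.list(tr$breakpoints)))
  jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Write gene models as BED12
#'
#' Converts the package's 1-based inclusive exon coordinates back to BED's
#' 0-based half-open convention, inverse of [read_gene_models()].
#'
#' @param genes List of `gene_model`.
#' @param path Output `.bed` path.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(genes, function(gm) {
    ex <- gm$exons
    chromStart <- min(ex$start) - 1L
    sizes <- ex$end - ex$start + 1L
    starts <- ex$start - 1L - chromStart
    paste(gm$scaffold, chromStart, max(ex$end), gm$gene, 0, gm$strand,
          chromStart, max(ex$end), "0,0,0", nrow(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Example gene layout around the simulated CNV
#'
#' Builds a five-gene annotation mirroring the canonical locus layout
#' relative to the configured CNV segments: a melanosome-maturation-style
#' gene fully inside the inner segment, a transporter-style gene straddling
#' the inner segment's right edge, a 5' fusion partner straddling the outer
#' right breakpoint, a 3' fusion partner straddling the outer left
#' breakpoint, and a gene fully outside the CNV.
#'
#' @param config A `sim_config`.
#' @return Named list of `gene_model`.
#' @export
example_gene_models <- function(config) {
  sc <- config$scaffold
  il <- config$inner$start; ir <- config$inner$end
  ol <- config$outer$start; or <- config$outer$end
  exon_run <- function(from, to, n = 3L) {
    cuts <- round(seq(from, to, length.out = 2L * n))
    data.frame(start = cuts[seq(1, 2 * n, by = 2)],
               end = cuts[seq(2, 2 * n, by = 2)])
  }
  list(
    Mlana = gene_model("Mlana", sc, "+",
                       exon_run(il + 2000, il + 8000, 4L)),
    Slc16a13 = gene_model("Slc16a13", sc, "-",
                          exon_run(ir - 4000, ir + 4000, 4L)),
    Ermp1 = gene_model("Ermp1", sc, "+",
                       exon_run(or - 6000, or + 6000, 5L)),
    Kiaa2026 = gene_model("Kiaa2026", sc, "-",
                          exon_run(ol - 6000, ol + 6000, 5L)),
    Ric1 = gene_model("Ric1", sc, "+",
                      exon_run(or + 12000, or + 20000, 3L)))
}
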