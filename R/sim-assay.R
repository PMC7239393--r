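#' Simulate a TaqMan-style copy-number assay plate
#'
#' Generates quadruplicate Ct values for a copy-number probe in the inner
#' CNV segment and a two-copy reference probe. The target Ct shifts by
#' `-log2(CN / calibrator CN)` relative to the calibrator so that
#' delta-delta-Ct quantification recovers the simulated copy number
#' exactly when `sd = 0`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param config A `sim_config` (`assay_sd` is the replicate noise).
#' @param calibrator Sample id used as calibrator; defaults to the first
#'   control. Its known copies are its simulated total inner copies.
#' @param replicates Replicates per probe (default 4, run in quadruplicate).
#' @param seed Optional seed.
#' @return An `assay_table`: long data frame `sample, phenotype, sex,
#'   probe, replicate, ct` with attributes `calibrator` and
#'   `calibrator_copies`.
#' @export
simulate_assay <- function(cohort, config, calibrator = NULL,
                           replicates = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- cohort$samples
  if (is.null(calibrator))
    calibrator <- samples$id[samples$phenotype == "non-Almond"][1]
  if (is.na(calibrator) || !calibrator %in% samples$id)
    stop("calibrator sample not found in cohort")
  c0 <- samples$total_inner_truth[samples$id == calibrator]
  ct_ref0 <- 25; ct_tgt0 <- 28
  rows <- vector("list", nrow(samples))
  for (k in seq_len(nrow(samples))) {
    cn <- samples$total_inner_truth[k]
    tgt <- ct_tgt0 - log2(cn / c0) + stats::rnorm(replicates, 0, config$assay_sd)
    ref <- ct_ref0 + stats::rnorm(replicates, 0, config$assay_sd)
    rows[[k]] <- data.frame(sample = samples$id[k],
                            phenotype = samples$phenotype[k],
                            sex = samples$sex[k],
                            probe = rep(c("target", "reference"),
                                        each = replicates),
                            replicate = rep(seq_len(replicates), 2L),
                            ct = c(tgt, ref))
  }
  out <- do.call(rbind, rows)
  if (any(out$ct <= 0)) stop("simulated Ct <= 0; lower the noise sd")
  structure(out, calibrator = calibrator, calibrator_copies = c0,
            class = c("assay_table", "data.frame"))
}

#' Simulate a qRT-PCR expression plate
#'
#' Per gene, each sample's target Ct is `baseline + group effect + noise`
#' and the reference-gene (beta-actin-style) Ct is `ref_baseline + noise`,
#' run in duplicate. A group effect of `-log2(F)` Ct units corresponds to an
#' F-fold expression increase after delta-delta-Ct quantification.
#'
#' @param groups Data frame `sample, group` (groups e.g. NA/DA/LA/HA).
#' @param effects Named list: per gene, a named numeric vector of Ct shifts
#'   by group (groups absent from the vector get shift 0).
#' @param config A `sim_config` (`expr_sd` is the replicate noise).
#' @param replicates Replicates per measurement (default 2, duplicates).
#' @param seed Optional seed.
#' @return A `ct_table`: long data frame
#'   `sample, group, gene, replicate, ct, ct_ref`.
#' @export
simulate_expression <- function(groups, effects, config, replicates = 2L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("sample", "group") %in% names(groups)))
  rows <- list()
  for (gene in names(effects)) {
    eff <- effects[[gene]]
    for (k in seq_len(nrow(groups))) {
      shift <- if (groups$group[k] %in% names(eff)) eff[[groups$group[k]]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = groups$sample[k], group = groups$group[k], gene = gene,
        replicate = seq_len(replicates),
        ct = 24 + shift + stats::rnorm(replicates, 0, config$expr_sd),
        ct_ref = 20 + stats::rnorm(replicates, 0, config$expr_sd))
    }
  }
  structure(do.call(rbind, rows), class = c("ct_table", "data.frame"))
}
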