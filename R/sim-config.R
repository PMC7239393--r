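#' Simulation configuration
#'
#' Study conditions for the synthetic cohort generator. Defaults emulate the
#' mapping panel (12 case vs 109 control genomes, cases mostly hemizygous
#' females) and place the nested CNV on a single 400-kb synthetic scaffold
#' at the printed locus coordinates shifted left by `coord_offset`, so the
#' published anchors stay usable at desk scale. Coverage 30x and per-base
#' error 0.5% are configuration defaults for a modern resequencing panel,
#' not reported values.
#'
#' @param seed Integer seed; every simulator call is deterministic given it.
#' @param n_case_female,n_case_male,n_control_female,n_control_male Cohort
#'   sizes by sex (defaults 10/2 cases, 55/54 controls).
#' @param coverage Mean per-copy sequencing depth (x) at baseline ploidy.
#' @param error_rate Per-base sequencing error rate in `[0, 1]`.
#' @param n_private_snvs Copy-private SNVs planted inside the inner segment.
#' @param assay_sd TaqMan replicate noise, Ct units.
#' @param expr_sd qPCR replicate noise, Ct units.
#' @param window Depth window size, bp.
#' @param scaffold Synthetic scaffold name.
#' @param scaffold_length Scaffold length, bp.
#' @param coord_offset Amount subtracted from printed coordinates to place
#'   the locus on the synthetic scaffold.
#' @param outer,inner Printed outer/inner CNV intervals (1-based inclusive,
#'   pre-offset). Defaults are the locus coordinates
#'   ScoHet5_227:5,181,467-5,259,256 and 5,201,091-5,226,635.
#' @param allele_series Named list mapping phenotype to per-chromosome
#'   `c(outer, inner)` copy counts for the affected Z. The canonical Almond
#'   allele is `c(7, 14)`.
#' @param background_maf Range of the shared background allele frequency.
#' @param clip_bg_rate Per-bp probability of a sporadic 1-read background
#'   clip.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_case_female = 10L, n_case_male = 2L,
                       n_control_female = 55L, n_control_male = 54L,
                       coverage = 30, error_rate = 0.005,
                       n_private_snvs = 4L,
                       assay_sd = 0.15, expr_sd = 0.3,
                       window = 100L,
                       scaffold = "ScoHet5_227",
                       scaffold_length = 400000L,
                       coord_offset = 5100000L,
                       outer = c(5181467L, 5259256L),
                       inner = c(5201091L, 5226635L),
                       allele_series = list(Almond = c(7L, 14L),
                                            Qualmond = c(3L, 6L),
                                            Faded = c(2L, 4L),
                                            "non-Almond" = c(1L, 1L)),
                       background_maf = c(0.1, 0.9),
                       clip_bg_rate = 1e-4) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  if (clip_bg_rate < 0 || clip_bg_rate > 1) stop("clip_bg_rate must lie in [0, 1]")
  outer_i <- genomic_interval(scaffold, outer[1] - coord_offset,
                              outer[2] - coord_offset)
  inner_i <- genomic_interval(scaffold, inner[1] - coord_offset,
                              inner[2] - coord_offset)
  if (!strictly_nested(outer_i, inner_i))
    stop("inner interval must be strictly nested in the outer interval")
  if (outer_i$end > scaffold_length)
    stop("CNV does not fit on the synthetic scaffold; increase scaffold_length")
  structure(list(seed = as.integer(seed),
                 n_case_female = n_case_female, n_case_male = n_case_male,
                 n_control_female = n_control_female,
                 n_control_male = n_control_male,
                 coverage = coverage, error_rate = error_rate,
                 n_private_snvs = n_private_snvs,
                 assay_sd = assay_sd, expr_sd = expr_sd,
                 window = as.integer(window),
                 scaffold = scaffold,
                 scaffold_length = as.integer(scaffold_length),
                 coord_offset = coord_offset,
                 outer = outer_i, inner = inner_i,
                 allele_series = allele_series,
                 background_maf = background_maf,
                 clip_bg_rate = clip_bg_rate),
            class = "sim_config")
}

#' Per-sample CNV truth
#'
#' Per-Z-chromosome outer and inner copy counts plus breakpoint positions.
#' `outer_copies`/`inner_copies` have one entry per Z chromosome (1 for a
#' female, 2 for a male); the inner count is always `>=` the outer count and
#' both are `>= 1`.
#'
#' @param config A `sim_config`.
#' @param outer_copies,inner_copies Integer vectors, one per Z chromosome.
#' @return Object of class `cnv_truth`.
#' @export
cnv_truth <- function(config, outer_copies, inner_copies) {
  stopifnot(length(outer_copies) == length(inner_copies),
            length(outer_copies) %in% 1:2)
  if (any(outer_copies < 1L)) stop("outer copy counts must be >= 1")
  if (any(inner_copies < outer_copies))
    stop("inner copy count must be >= outer copy count")
  structure(list(outer = config$outer, inner = config$inner,
                 outer_copies = as.integer(outer_copies),
                 inner_copies = as.integer(inner_copies),
                 breakpoints = c(outer_left = config$outer$start,
                                 inner_left = config$inner$start,
                                 inner_right = config$inner$end,
                                 outer_right = config$outer$end)),
            class = "cnv_truth")
}

truth_baseline <- function(truth) length(truth$outer_copies)
truth_total_inner <- function(truth) sum(truth$inner_copies)
truth_total_outer <- function(truth) sum(truth$outer_copies)

#' Simulate a two-cohort ZW/ZZ cohort with CNV truth
#'
#' Assigns each sample a phenotype-determined per-chromosome copy-number
#' truth: phenotypes in `config$allele_series` carry the configured
#' expansion on one Z (females on their single Z; males heterozygous unless
#' listed in `homozygous_ids`), all other chromosomes carry `c(1, 1)`.
#'
#' @param config A `sim_config`.
#' @param case_phenotype Phenotype label for cases (default `"Almond"`).
#' @param homozygous_ids Sample ids (among case males) to make homozygous.
#' @return List with `samples` (a `sample_sheet` plus truth columns) and
#'   `truth` (named list of `cnv_truth`).
#' @export
simulate_cohort <- function(config, case_phenotype = "Almond",
                            homozygous_ids = character(0)) {
  n_cases <- config$n_case_female + config$n_case_male
  n_ctrl <- config$n_control_female + config$n_control_male
  if (n_cases < 1L || n_ctrl < 1L) stop("both cohorts must be non-empty")
  id <- c(sprintf("case_%02d", seq_len(n_cases)),
          sprintf("ctrl_%03d", seq_len(n_ctrl)))
  sex <- c(rep(c("female", "male"), c(config$n_case_female, config$n_case_male)),
           rep(c("female", "male"),
               c(config$n_control_female, config$n_control_male)))
  phenotype <- rep(c(case_phenotype, "non-Almond"), c(n_cases, n_ctrl))
  samples <- sample_sheet(id, phenotype, sex,
                          phenotypes = unique(c(phenotype, names(config$allele_series))))
  truth <- vector("list", nrow(samples)); names(truth) <- samples$id
  for (k in seq_len(nrow(samples))) {
    alle <- config$allele_series[[samples$phenotype[k]]]
    if (is.null(alle)) alle <- c(1L, 1L)
    nz <- samples$z_baseline[k]
    hom <- samples$id[k] %in% homozygous_ids
    o <- i <- rep(1L, nz)
    naff <- if (samples$phenotype[k] == "non-Almond") 0L
            else if (hom) nz else 1L
    if (naff > 0L) { o[seq_len(naff)] <- alle[1]; i[seq_len(naff)] <- alle[2] }
    truth[[k]] <- cnv_truth(config, o, i)
  }
  samples$total_inner_truth <- vapply(truth, truth_total_inner, integer(1))
  list(samples = samples, truth = truth)
}
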