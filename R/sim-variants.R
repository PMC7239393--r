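#' Simulate allelic depths inside the CNV region
#'
#' Emulates a pileup-based variant table over the CNV region for a cohort
#' with known copy-number truth. Three kinds of sites are generated:
#'
#' * `n_private_snvs` copy-private SNVs inside the inner segment: every
#'   sample carrying an expanded allele has the variant on exactly one of
#'   its inner copies, so its expected allelic fraction is
#'   `1 / (total inner copies)` (1/14, about 7%, for a hemizygous female
#'   with the canonical expansion); samples without the expansion do not
#'   carry it.
#' * `n_background` biallelic population SNVs with an allele frequency
#'   shared between cohorts. Population alleles are assigned per ancestral
#'   Z chromosome; because the CNV copies on a chromosome are identical by
#'   descent, a carrier chromosome carries the allele on all of its
#'   copies, so a sample's expected allelic fraction is the copy-weighted
#'   carrier share.
#' * `n_multi` multiallelic population sites with two shared alternate
#'   alleles assigned the same way.
#'
#' Per sample and site, total depth is `DP ~ Poisson(coverage * local
#' copies / baseline)` (local copies at the site position) and the reads
#' supporting each carried allele are binomial in its copy fraction.
#' Sequencing errors add `Binomial(DP, error_rate)` reads spread uniformly
#' over the three non-reference bases; error bases join the site's allele
#' list when observed in any sample.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param config A `sim_config`.
#' @param n_background,n_multi Numbers of shared background sites.
#' @param seed Optional seed.
#' @return A `variant_table` with attribute `planted`, a data frame of the
#'   planted copy-private (pos, allele) pairs.
#' @export
simulate_allele_depths <- function(cohort, config, n_background = 30L,
                                   n_multi = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- cohort$samples; truth <- cohort$truth
  bases <- c("A", "C", "G", "T")
  inner <- config$inner; outer <- config$outer

  npriv <- config$n_private_snvs
  pos_priv <- if (npriv > 0)
    round(seq(inner$start + 500, inner$end - 500, length.out = npriv)) else integer(0)
  pos_bg <- if (n_background > 0)
    sort(sample(setdiff(seq(outer$start, outer$end), pos_priv), n_background)) else integer(0)
  pos_multi <- if (n_multi > 0)
    sort(sample(setdiff(seq(outer$start, outer$end), c(pos_priv, pos_bg)),
                n_multi)) else integer(0)

  site_pos <- c(pos_priv, pos_bg, pos_multi)
  site_kind <- rep(c("private", "background", "multi"),
                   c(npriv, n_background, n_multi))
  o <- order(site_pos); site_pos <- site_pos[o]; site_kind <- site_kind[o]
  ns <- length(site_pos)
  ref <- sample(bases, ns, replace = TRUE)
  freq_bg <- stats::runif(ns, 0.05, 0.5)   # shared population frequency

  scaffold <- rep(config$scaffold, ns)
  alleles <- vector("list", ns); ad <- vector("list", ns)
  dp <- matrix(0L, ns, nrow(samples), dimnames = list(NULL, samples$id))
  planted <- data.frame(pos = integer(0), allele = character(0))

  for (i in seq_len(ns)) {
    alts <- setdiff(bases, ref[i])
    carried <- switch(site_kind[i],
                      private = alts[1],
                      background = alts[1],
                      multi = alts[1:2])
    if (site_kind[i] == "private")
      planted <- rbind(planted, data.frame(pos = site_pos[i], allele = carried))
    counts <- matrix(0L, nrow(samples), 4L,
                     dimnames = list(samples$id, bases))
    for (k in seq_len(nrow(samples))) {
      tr <- truth[[k]]
      loc <- chrom_local_copies(tr, site_pos[i])  # per-chromosome copies
      ktot <- sum(loc)
      base_k <- truth_baseline(tr)
      dpk <- stats::rpois(1, config$coverage * ktot / base_k)
      dp[i, k] <- dpk
      if (dpk == 0L) next
      # copy-weighted fraction of each non-ref allele
      if (site_kind[i] == "private") {
        ccar <- if (any(tr$inner_copies > tr$outer_copies)) 1L else 0L
        cfrac <- stats::setNames(ccar / ktot, carried)
      } else {
        # each ancestral chromosome carries one allele; all its copies do
        pcar <- freq_bg[i] / length(carried)
        chrom_allele <- sample(c(carried, "ref"), length(loc),
                               replace = TRUE,
                               prob = c(rep(pcar, length(carried)),
                                        1 - freq_bg[i]))
        cfrac <- vapply(carried, function(al)
          sum(loc[chrom_allele == al]) / ktot, numeric(1))
      }
      for (al in names(cfrac)) if (cfrac[[al]] > 0)
        counts[k, al] <- counts[k, al] + stats::rbinom(1, dpk, cfrac[[al]])
      nerr <- stats::rbinom(1, dpk, config$error_rate)
      if (nerr > 0L) {
        eb <- sample(alts, nerr, replace = TRUE)
        for (al in alts) counts[k, al] <- counts[k, al] + sum(eb == al)
      }
      used <- sum(counts[k, alts])
      if (used > dpk) {  # cap at DP; trim error reads first
        over <- used - dpk
        for (al in rev(alts)) {
          trim <- min(over, counts[k, al]); counts[k, al] <- counts[k, al] - trim
          over <- over - trim; if (over == 0L) break
        }
      }
      counts[k, ref[i]] <- dpk - sum(counts[k, alts])
    }
    seen_alts <- alts[colSums(counts[, alts, drop = FALSE]) > 0]
    # keep carried alleles in the list even if unobserved this replicate
    seen_alts <- union(intersect(alts, carried), seen_alts)
    alleles[[i]] <- c(ref[i], seen_alts)
    ad[[i]] <- counts[, alleles[[i]], drop = FALSE]
    colnames(ad[[i]]) <- NULL
  }
  vt <- variant_table(scaffold, site_pos, alleles, ad, dp, samples$id)
  attr(vt, "planted") <- planted
  vt
}

#' Simulate case/control genotype data for the differentiation scan
#'
#' Background sites draw both cohorts' allele counts from one shared
#' frequency (uniform over `config$background_maf`); causal-region sites
#' draw cases at `case_freq` and controls at `control_freq`. Genotypes
#' respect Z ploidy: a female contributes one allele, a male two. Allelic
#' depths encode the genotype (`AD = (ploidy - dose, dose)`, `DP = ploidy`).
#'
#' @param cohort Result of [simulate_cohort()] (any truth; only ids/sex are
#'   used).
#' @param config A `sim_config`.
#' @param n_sites Number of background sites.
#' @param n_causal Number of causal-region sites (0 gives a pure null).
#' @param case_freq,control_freq Alternate-allele frequencies at causal
#'   sites (equal values give divergence 0).
#' @param causal_region `genomic_interval` hosting the causal sites
#'   (default: the configured inner segment).
#' @param seed Optional seed.
#' @return A `variant_table`; causal positions in attribute `causal_pos`.
#' @export
simulate_differentiated_genotypes <- function(cohort, config,
                                              n_sites = 2000L, n_causal = 0L,
                                              case_freq = 1, control_freq = 0,
                                              causal_region = NULL,
                                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(causal_region)) causal_region <- config$inner
  samples <- cohort$samples
  is_case <- samples$phenotype != "non-Almond"
  ploidy <- samples$z_baseline
  bg_all <- setdiff(seq_len(config$scaffold_length),
                    seq(causal_region$start, causal_region$end))
  pos_bg <- sort(sample(bg_all, n_sites))
  pos_ca <- if (n_causal > 0)
    sort(sample(seq(causal_region$start, causal_region$end), n_causal)) else integer(0)
  pos <- c(pos_bg, pos_ca); o <- order(pos); pos <- pos[o]
  kind <- c(rep("bg", n_sites), rep("causal", n_causal))[o]
  ns <- length(pos)
  f_bg <- stats::runif(ns, config$background_maf[1], config$background_maf[2])
  alleles <- rep(list(c("A", "G")), ns)
  ad <- vector("list", ns)
  dp <- matrix(rep(as.integer(ploidy), each = ns), ns, nrow(samples),
               dimnames = list(NULL, samples$id))
  for (i in seq_len(ns)) {
    f <- if (kind[i] == "bg") rep(f_bg[i], nrow(samples)) else
      ifelse(is_case, case_freq, control_freq)
    dose <- stats::rbinom(nrow(samples), ploidy, f)
    ad[[i]] <- matrix(as.integer(c(ploidy - dose, dose)), nrow(samples), 2L,
                      dimnames = list(samples$id, NULL))
  }
  vt <- variant_table(rep(config$scaffold, ns), pos, alleles, ad, dp,
                      samples$id)
  attr(vt, "causal_pos") <- pos[kind == "causal"]
  vt
}
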