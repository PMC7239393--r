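#' Two-binomial likelihood-ratio test for allele-frequency differentiation
#'
#' Contrasts case and control alternate-allele counts at one site. With
#' `a1` alternate alleles of `n1` in cases, `a2` of `n2` in controls,
#' sample frequencies `p1 = a1/n1`, `p2 = a2/n2` and pooled
#' `p0 = (a1+a2)/(n1+n2)`, the statistic is
#' `G = 2 * (l(p1; a1,n1) + l(p2; a2,n2) - l(p0; a1,n1) - l(p0; a2,n2))`
#' where `l` is the binomial log-likelihood with the `0*log(0) = 0`
#' convention. The p-value is the upper chi-square(1) tail at `G`. This is
#' a hard-count approximation to genotype-likelihood-based differentiation
#' statistics such as pFst.
#'
#' @param a1,n1 Case alternate count and total allele count.
#' @param a2,n2 Control alternate count and total allele count.
#' @return List with `G` and `p` (vectorized over sites).
#' @examples
#' lrt_site(5, 10, 10, 20)   # equal frequencies: G = 0, p = 1
#' lrt_site(10, 10, 0, 10)   # complete divergence
#' @export
lrt_site <- function(a1, n1, a2, n2) {
  if (any(n1 < 1) || any(n2 < 1)) stop("allele totals must be >= 1")
  if (any(a1 < 0 | a1 > n1) || any(a2 < 0 | a2 > n2))
    stop("allele counts must satisfy 0 <= a <= n")
  p1 <- a1 / n1; p2 <- a2 / n2; p0 <- (a1 + a2) / (n1 + n2)
  # grouped per cohort so G is exactly 0 when p1 == p2 == p0
  G <- 2 * ((binom_ll(a1, n1, p1) - binom_ll(a1, n1, p0)) +
              (binom_ll(a2, n2, p2) - binom_ll(a2, n2, p0)))
  G <- pmax(G, 0)  # clip tiny negative round-off
  list(G = G, p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

# binomial log-likelihood kernel, 0*log(0) == 0
binom_ll <- function(a, n, p) {
  t1 <- ifelse(a == 0, 0, a * log(p))
  t2 <- ifelse(n - a == 0, 0, (n - a) * log(1 - p))
  t1 + t2
}

#' Genome-wide differentiation scan
#'
#' Runs [lrt_site()] at every site of a variant table. Allele counting is
#' sex-aware on Z: a female contributes 1 allele, a male 2; a sample's
#' alternate dosage at a site is called from its allelic depths as
#' `round(ploidy * AD_alt / DP)` clipped to `[0, ploidy]`. Multiallelic
#' sites are reduced to reference vs the most common alternate (by summed
#' reads); samples with `DP = 0`/missing data are excluded at that site,
#' and sites where either cohort has no callable sample are dropped with a
#' logged reason.
#'
#' @param vt A `variant_table`.
#' @param samples A `sample_sheet` covering the table's samples.
#' @param case_phenotypes Phenotype labels forming the case cohort; all
#'   other samples are controls.
#' @return A `scan_result` data frame with columns
#'   `scaffold, pos, a1, n1, a2, n2, G, p, minus_log10_p` and attributes
#'   `threshold` (Bonferroni p-threshold over tested sites), `n_tested`
#'   and `skipped`.
#' @export
genome_scan <- function(vt, samples, case_phenotypes = "Almond") {
  idx <- match(vt$samples, samples$id)
  if (anyNA(idx)) stop("samples missing from sample sheet: ",
                       paste(vt$samples[is.na(idx)], collapse = ", "))
  ploidy <- samples$z_baseline[idx]
  is_case <- samples$phenotype[idx] %in% case_phenotypes
  if (!any(is_case) || all(is_case)) stop("both cohorts need >= 1 sample")
  ns <- n_sites(vt)
  a1 <- n1 <- a2 <- n2 <- integer(ns)
  keep <- logical(ns); skipped <- character(0)
  for (i in seq_len(ns)) {
    adm <- vt$ad[[i]]
    altm <- adm[, -1, drop = FALSE]
    alt_idx <- which.max(colSums(altm, na.rm = TRUE))
    altd <- altm[, alt_idx]
    dpv <- vt$dp[i, ]
    ok <- !is.na(altd) & !is.na(dpv) & dpv > 0
    dose <- pmin(pmax(round(ploidy * altd / dpv), 0), ploidy)
    c1 <- ok & is_case; c2 <- ok & !is_case
    if (!any(c1) || !any(c2)) {
      skipped <- c(skipped, sprintf("%s:%d all-missing cohort",
                                    vt$scaffold[i], vt$pos[i]))
      next
    }
    a1[i] <- sum(dose[c1]); n1[i] <- sum(ploidy[c1])
    a2[i] <- sum(dose[c2]); n2[i] <- sum(ploidy[c2])
    keep[i] <- TRUE
  }
  lr <- lrt_site(a1[keep], n1[keep], a2[keep], n2[keep])
  out <- data.frame(scaffold = vt$scaffold[keep], pos = vt$pos[keep],
                    a1 = a1[keep], n1 = n1[keep],
                    a2 = a2[keep], n2 = n2[keep],
                    G = lr$G, p = lr$p,
                    minus_log10_p = -log10(lr$p))
  structure(out, threshold = significance_threshold(sum(keep)),
            n_tested = sum(keep), skipped = skipped,
            class = c("scan_result", "data.frame"))
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_sites Number of tested sites (`>= 1`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_sites`.
#' @export
significance_threshold <- function(n_sites, alpha = 0.05) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  alpha / n_sites
}

#' Merge significant scan sites into candidate regions
#'
#' Sites below the significance threshold are merged into intervals when
#' within `merge_gap` bp of each other (via `IRanges::reduce`); intervals
#' are ranked by their peak `-log10(p)`, ties broken by scaffold order then
#' position.
#'
#' @param scan A `scan_result`.
#' @param merge_gap Merge distance in bp (default 10 kb).
#' @param threshold p-value threshold; defaults to the scan's Bonferroni
#'   attribute.
#' @return Data frame `scaffold, start, end, n_sites, peak_minus_log10_p,
#'   peak_pos`, best region first; zero rows when nothing is significant.
#' @export
candidate_region <- function(scan, merge_gap = 10000, threshold = NULL) {
  if (nrow(scan) == 0L) stop("empty scan")
  if (is.null(threshold)) threshold <- attr(scan, "threshold")
  sig <- scan[scan$p < threshold, , drop = FALSE]
  empty <- data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), n_sites = integer(0),
                      peak_minus_log10_p = numeric(0), peak_pos = numeric(0))
  if (nrow(sig) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(sig$scaffold,
                               IRanges::IRanges(sig$pos, sig$pos))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1)
  hit <- GenomicRanges::findOverlaps(gr, red)
  out <- do.call(rbind, lapply(seq_along(red), function(j) {
    rows <- sig[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == j], ,
                drop = FALSE]
    peak <- rows[which.max(rows$minus_log10_p), ]
    data.frame(scaffold = as.character(GenomicRanges::seqnames(red[j])),
               start = GenomicRanges::start(red[j]),
               end = GenomicRanges::end(red[j]),
               n_sites = nrow(rows),
               peak_minus_log10_p = peak$minus_log10_p,
               peak_pos = peak$pos)
  }))
  out[order(-out$peak_minus_log10_p, out$scaffold, out$start), , drop = FALSE]
}

#' Scan coding regions for case-fixed differences
#'
#' Returns sites inside exons where some alternate allele is carried by
#' every case (dosage `>= 1`) and by no control. A site with any missing
#' genotype (DP 0 or missing AD) in either cohort is ineligible.
#'
#' @param vt A `variant_table`.
#' @param samples A `sample_sheet`.
#' @param coding_mask List of `gene_model` restricting the scan to exons.
#' @param case_phenotypes Phenotype labels forming the case cohort.
#' @return Data frame `scaffold, pos, allele` (zero rows when no fixed
#'   difference exists).
#' @export
fixed_difference_scan <- function(vt, samples, coding_mask,
                                  case_phenotypes = "Almond") {
  idx <- match(vt$samples, samples$id)
  ploidy <- samples$z_baseline[idx]
  is_case <- samples$phenotype[idx] %in% case_phenotypes
  in_coding <- rep(FALSE, n_sites(vt))
  for (gm in coding_mask) for (e in seq_len(nrow(gm$exons)))
    in_coding <- in_coding | (vt$scaffold == gm$scaffold &
                                vt$pos >= gm$exons$start[e] &
                                vt$pos <= gm$exons$end[e])
  hits <- list()
  for (i in which(in_coding)) {
    adm <- vt$ad[[i]]; dpv <- vt$dp[i, ]
    if (any(is.na(adm)) || any(is.na(dpv)) || any(dpv == 0)) next
    for (j in seq_along(vt$alleles[[i]])[-1]) {
      dose <- pmin(pmax(round(ploidy * adm[, j] / dpv), 0), ploidy)
      if (all(dose[is_case] >= 1) && all(dose[!is_case] == 0))
        hits[[length(hits) + 1L]] <- data.frame(scaffold = vt$scaffold[i],
                                                pos = vt$pos[i],
                                                allele = vt$alleles[[i]][j])
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(scaffold = character(0), pos = integer(0),
               allele = character(0))
}
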