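#' Retain alleles above a per-sample allelic-fraction threshold
#'
#' Applies the low-frequency retention rule: an alternate allele is
#' retained for a sample when `AD/DP > min_frac` (strictly greater). The
#' default 4% keeps a variant private to 1 of 14 locus copies (about 7%
#' allelic fraction) while discarding typical sequencing-error support.
#' Applied per sample and per alternate allele; samples with `DP = 0` or
#' missing AD are skipped at that site.
#'
#' @param vt A `variant_table`.
#' @param region Optional `genomic_interval` restriction.
#' @param min_frac Retention threshold on AD/DP (default 0.04).
#' @param samples Optional character vector restricting which samples are
#'   evaluated.
#' @return A `retained_alleles` data frame: `site, scaffold, pos,
#'   n_alleles, allele, sample, ad, dp, frac`.
#' @export
filter_allelic_fraction <- function(vt, region = NULL, min_frac = 0.04,
                                    samples = NULL) {
  vt <- subset_region(vt, region)
  if (is.null(samples)) samples <- vt$samples
  sj <- match(samples, vt$samples)
  if (anyNA(sj)) stop("unknown sample(s): ",
                      paste(samples[is.na(sj)], collapse = ", "))
  rows <- list()
  for (i in seq_len(n_sites(vt))) {
    al <- vt$alleles[[i]]; adm <- vt$ad[[i]]; dpv <- vt$dp[i, ]
    for (j in seq_along(sj)) {
      k <- sj[j]
      if (is.na(dpv[k]) || dpv[k] == 0L || anyNA(adm[k, ])) next
      for (a in seq_along(al)[-1]) {
        frac <- adm[k, a] / dpv[k]
        if (frac > min_frac)
          rows[[length(rows) + 1L]] <- data.frame(
            site = i, scaffold = vt$scaffold[i], pos = vt$pos[i],
            n_alleles = length(al), allele = al[a], sample = samples[j],
            ad = adm[k, a], dp = dpv[k], frac = frac)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), scaffold = character(0), pos = integer(0),
               n_alleles = integer(0), allele = character(0),
               sample = character(0), ad = integer(0), dp = integer(0),
               frac = numeric(0))
  structure(out, min_frac = min_frac,
            class = c("retained_alleles", "data.frame"))
}

#' Case-private alleles at biallelic sites
#'
#' For sites with exactly two alleles, returns the alternate alleles whose
#' retained frequency is nonzero in the case cohort and zero in controls
#' (the cohort-wise frequency comparison branch of the scan).
#'
#' @param retained A `retained_alleles` data frame.
#' @param cases,controls Character vectors of sample ids.
#' @return Data frame `scaffold, pos, allele, n_cases_retained`.
#' @export
biallelic_private_alleles <- function(retained, cases, controls) {
  bi <- retained[retained$n_alleles == 2L, , drop = FALSE]
  if (nrow(bi) == 0L)
    return(data.frame(scaffold = character(0), pos = integer(0),
                      allele = character(0), n_cases_retained = integer(0)))
  key <- paste(bi$scaffold, bi$pos, bi$allele)
  out <- do.call(rbind, lapply(split(bi, key), function(g) {
    n_case <- sum(g$sample %in% cases)
    n_ctrl <- sum(g$sample %in% controls)
    if (n_case >= 1L && n_ctrl == 0L)
      data.frame(scaffold = g$scaffold[1], pos = g$pos[1],
                 allele = g$allele[1], n_cases_retained = n_case)
  }))
  if (is.null(out))
    return(data.frame(scaffold = character(0), pos = integer(0),
                      allele = character(0), n_cases_retained = integer(0)))
  rownames(out) <- NULL
  out[order(out$pos, out$allele), , drop = FALSE]
}

#' Recurrence scan over multiallelic sites
#'
#' Builds the binary presence matrix (rows = (site, allele), columns =
#' case samples; 1 when at least one read supports the allele — no
#' fraction threshold, deliberately laxer than the retention filter) and
#' returns rows whose presence sum reaches `min_cases`. Missing data count
#' as absent.
#'
#' @param vt A `variant_table` (region-restrict beforehand if needed).
#' @param cases Character vector of case sample ids.
#' @param min_cases Minimum number of cases carrying the allele
#'   (default 3).
#' @param retained Optional `retained_alleles`; when given, only alleles
#'   retained in at least one case enter the matrix (the pipeline default);
#'   when `NULL`, every alternate allele at a multiallelic site is scanned.
#' @return Data frame `scaffold, pos, allele, n_cases_present` with
#'   attribute `presence` (the full binary matrix).
#' @export
recurrence_scan <- function(vt, cases, min_cases = 3L, retained = NULL) {
  cj <- match(cases, vt$samples)
  if (anyNA(cj)) stop("unknown case sample(s)")
  out <- list()
  keep_key <- if (!is.null(retained))
    unique(paste(retained$scaffold[retained$sample %in% cases],
                 retained$pos[retained$sample %in% cases],
                 retained$allele[retained$sample %in% cases]))
  mat <- list()
  for (i in seq_len(n_sites(vt))) {
    al <- vt$alleles[[i]]
    if (length(al) <= 2L) next
    adm <- vt$ad[[i]]
    for (a in seq_along(al)[-1]) {
      key <- paste(vt$scaffold[i], vt$pos[i], al[a])
      if (!is.null(retained) && !key %in% keep_key) next
      present <- as.integer(!is.na(adm[cj, a]) & adm[cj, a] >= 1L)
      mat[[key]] <- present
      if (sum(present) >= min_cases)
        out[[key]] <- data.frame(scaffold = vt$scaffold[i], pos = vt$pos[i],
                                 allele = al[a],
                                 n_cases_present = sum(present))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(0), pos = integer(0),
               allele = character(0), n_cases_present = integer(0))
  rownames(res) <- NULL
  presence <- if (length(mat))
    matrix(unlist(mat), ncol = length(cases), byrow = TRUE,
           dimnames = list(names(mat), cases))
  else matrix(0L, 0, length(cases), dimnames = list(NULL, cases))
  structure(res[order(res$pos, res$allele), , drop = FALSE],
            presence = presence, class = c("data.frame"))
}

#' Cross-check candidate alleles against the control cohort
#'
#' Removes any candidate (site, allele) with at least one supporting read
#' in any control sample; survivors are reported as case-specific.
#'
#' @param candidates Data frame with `scaffold, pos, allele` (from
#'   [recurrence_scan()] or [biallelic_private_alleles()]).
#' @param vt The `variant_table` holding control depths.
#' @param controls Character vector of control sample ids.
#' @return The candidates with added `n_controls_present` and `verdict`
#'   (`"case-specific"` rows only).
#' @export
control_cross_check <- function(candidates, vt, controls) {
  kj <- match(controls, vt$samples)
  if (anyNA(kj)) stop("unknown control sample(s)")
  if (nrow(candidates) == 0L) {
    candidates$n_controls_present <- integer(0)
    candidates$verdict <- character(0)
    return(candidates)
  }
  n_ctrl <- integer(nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    i <- which(vt$scaffold == candidates$scaffold[r] &
                 vt$pos == candidates$pos[r])[1]
    a <- match(candidates$allele[r], vt$alleles[[i]])
    n_ctrl[r] <- if (is.na(a)) 0L else
      sum(!is.na(vt$ad[[i]][kj, a]) & vt$ad[[i]][kj, a] >= 1L)
  }
  candidates$n_controls_present <- n_ctrl
  candidates$verdict <- ifelse(n_ctrl == 0L, "case-specific", "shared")
  candidates[candidates$verdict == "case-specific", , drop = FALSE]
}

#' Full paralog-aware low-frequency variant scan
#'
#' Chains the scan: region restriction, allelic-fraction retention in
#' cases, routing of sites by allele count (biallelic sites through the
#' cohort frequency comparison, multiallelic sites through the
#' presence-recurrence scan), and the control cross-check. Output is
#' invariant to sample order.
#'
#' @param vt A `variant_table`.
#' @param samples A `sample_sheet`.
#' @param region Optional `genomic_interval` (the CNV region).
#' @param case_phenotypes Phenotypes forming the case cohort.
#' @param min_frac Retention threshold (default 0.04).
#' @param min_cases Recurrence threshold (default 3).
#' @return Data frame `scaffold, pos, allele, branch, n_cases_present,
#'   max_case_fraction, n_controls_present, verdict` with only
#'   case-specific alleles; zero rows reproduce a negative scan.
#' @export
paralog_scan <- function(vt, samples, region = NULL,
                         case_phenotypes = "Almond",
                         min_frac = 0.04, min_cases = 3L) {
  vt <- subset_region(vt, region)
  cases <- sort(samples$id[samples$phenotype %in% case_phenotypes])
  controls <- sort(setdiff(samples$id, cases))
  retained <- filter_allelic_fraction(vt, min_frac = min_frac,
                                      samples = cases)
  bi <- biallelic_private_alleles(
    rbind(retained, filter_allelic_fraction(vt, min_frac = min_frac,
                                            samples = controls)),
    cases, controls)
  multi <- recurrence_scan(vt, cases, min_cases = min_cases,
                           retained = retained)
  multi_ok <- control_cross_check(multi, vt, controls)
  frac_of <- function(df) vapply(seq_len(nrow(df)), function(r) {
    sub <- retained[retained$pos == df$pos[r] & retained$allele == df$allele[r], ]
    if (nrow(sub)) max(sub$frac) else NA_real_
  }, numeric(1))
  out <- rbind(
    if (nrow(bi)) data.frame(scaffold = bi$scaffold, pos = bi$pos,
                             allele = bi$allele, branch = "biallelic",
                             n_cases_present = bi$n_cases_retained,
                             n_controls_present = 0L),
    if (nrow(multi_ok)) data.frame(scaffold = multi_ok$scaffold,
                                   pos = multi_ok$pos,
                                   allele = multi_ok$allele,
                                   branch = "multiallelic",
                                   n_cases_present = multi_ok$n_cases_present,
                                   n_controls_present = multi_ok$n_controls_present))
  if (is.null(out))
    return(data.frame(scaffold = character(0), pos = integer(0),
                      allele = character(0), branch = character(0),
                      n_cases_present = integer(0),
                      max_case_fraction = numeric(0),
                      n_controls_present = integer(0),
                      verdict = character(0)))
  out$max_case_fraction <- frac_of(out)
  out$verdict <- "case-specific"
  out <- out[, c("scaffold", "pos", "allele", "branch", "n_cases_present",
                 "max_case_fraction", "n_controls_present", "verdict")]
  rownames(out) <- NULL
  out[order(out$pos, out$allele), , drop = FALSE]
}
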