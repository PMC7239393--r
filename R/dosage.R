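#' Delta-delta-Ct copy-number quantification
#'
#' Per sample, `dCt = mean(Ct_target) - mean(Ct_reference)`; against the
#' calibrator of known copy count `c0`, `ddCt = dCt_sample - dCt_calibrator`
#' and the continuous copy-number estimate is `c0 * 2^(-ddCt)`, rounded for
#' the integer estimate.
#'
#' @param assay An `assay_table` (long: `sample, phenotype, sex, probe,
#'   replicate, ct`) with attributes `calibrator` and `calibrator_copies`,
#'   or those supplied explicitly.
#' @param calibrator,calibrator_copies Override the table attributes.
#' @return A `copy_number_estimates` data frame: `sample, phenotype, sex,
#'   dct, ddct, cn_continuous, cn_integer`.
#' @export
quantify_copies <- function(assay, calibrator = attr(assay, "calibrator"),
                            calibrator_copies = attr(assay, "calibrator_copies")) {
  if (is.null(calibrator) || is.null(calibrator_copies))
    stop("calibrator sample and its known copy count are required")
  if (!all(c("target", "reference") %in% assay$probe))
    stop("assay table needs 'target' and 'reference' probes")
  if (!calibrator %in% assay$sample) stop("calibrator absent from assay table")
  per_sample <- function(s) {
    tgt <- assay$ct[assay$sample == s & assay$probe == "target"]
    ref <- assay$ct[assay$sample == s & assay$probe == "reference"]
    if (!length(tgt) || !length(ref))
      stop("sample ", s, " lacks target or reference replicates")
    mean(tgt) - mean(ref)
  }
  ids <- unique(assay$sample)
  dct <- vapply(ids, per_sample, numeric(1))
  ddct <- dct - dct[[calibrator]]
  cn <- calibrator_copies * 2^(-ddct)
  meta <- assay[match(ids, assay$sample), c("sample", "phenotype", "sex")]
  structure(data.frame(meta, dct = unname(dct), ddct = unname(ddct),
                       cn_continuous = unname(cn),
                       cn_integer = as.integer(round(cn))),
            class = c("copy_number_estimates", "data.frame"))
}

#' Rank-sum (Wilcoxon/Mann-Whitney) test with an exact small-sample path
#'
#' Two-sided test of location difference. Tie-free data with both group
#' sizes at most 25 use the exact Mann-Whitney null distribution
#' (`stats::pwilcox`). Tied data are handled exactly by full enumeration of
#' group assignments (midrank statistic) when `choose(n1+n2, n1)` is below
#' `enum_cap`, and by a fixed-seed permutation estimate (20,000 draws,
#' global RNG state untouched) for tied samples up to 25 per group beyond
#' the enumeration budget; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric vectors.
#' @param enum_cap Enumeration budget (default 2e5 assignments).
#' @return List `statistic` (Mann-Whitney U of `x`), `p`, `method`.
#' @export
rank_sum_test <- function(x, y, enum_cap = 2e5) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 <= 25L && n2 <= 25L) {
    lo <- stats::pwilcox(U, n1, n2)
    hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = U, p = p, method = "exact"))
  }
  if (ties && choose(n1 + n2, n1) <= enum_cap) {
    combos <- utils::combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    Us <- apply(combos, 2, function(idx)
      sum(rk[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(statistic = U, p = p, method = "enumeration"))
  }
  if (ties && n1 <= 25L && n2 <= 25L) {
    # fixed-seed permutation null; restore the caller's RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(20201L)
    mu <- n1 * n2 / 2
    nperm <- 20000L
    Us <- replicate(nperm, {
      idx <- sample.int(n1 + n2, n1)
      sum(rk[idx]) - n1 * (n1 + 1) / 2
    })
    p <- (1 + sum(abs(Us - mu) >= abs(U - mu) - 1e-9)) / (nperm + 1)
    return(list(statistic = U, p = p, method = "permutation"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- U - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = U, p = p, method = "normal")
}

#' Pairwise copy-number / phenotype association
#'
#' Runs the two-sided rank-sum test for every pair of phenotype groups and
#' applies Bonferroni correction over the number of tested pairs. Because
#' the family could equally be defined as "each phenotype against the
#' wild-type group only", the attribute `n_vs_baseline` reports that
#' alternative correction denominator alongside `n_pairs`.
#'
#' @param estimates A `copy_number_estimates` (or any data frame with the
#'   value/group columns named below).
#' @param value_col,group_col Column names (defaults `cn_continuous`,
#'   `phenotype`).
#' @param baseline Wild-type group label (default `"non-Almond"`).
#' @return List with `p_raw` and `p_bonferroni` (symmetric matrices;
#'   groups of size 0 are skipped with a logged reason in attribute
#'   `skipped`), `n_pairs`, `n_vs_baseline`.
#' @export
phenotype_association <- function(estimates, value_col = "cn_continuous",
                                  group_col = "phenotype",
                                  baseline = "non-Almond") {
  groups <- split(estimates[[value_col]], estimates[[group_col]])
  groups <- groups[order(names(groups))]
  skipped <- names(groups)[lengths(groups) == 0L]
  groups <- groups[lengths(groups) > 0L]
  gn <- names(groups)
  if (length(gn) < 2L) stop("need >= 2 non-empty phenotype groups")
  p <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  for (i in seq_along(gn)) for (j in seq_along(gn)) if (i < j) {
    pij <- rank_sum_test(groups[[i]], groups[[j]])$p
    p[i, j] <- p[j, i] <- pij
  }
  n_pairs <- choose(length(gn), 2)
  n_vs_baseline <- if (baseline %in% gn) length(gn) - 1L else NA_integer_
  structure(list(p_raw = p, p_bonferroni = pmin(p * n_pairs, 1),
                 n_pairs = n_pairs, n_vs_baseline = n_vs_baseline),
            skipped = skipped, class = "phenotype_association")
}

#' Relative expression by delta-delta-Ct
#'
#' Per sample and gene, `dCt = mean(Ct_gene) - mean(Ct_reference)`
#' (replicates averaged first); the fold change of a sample relative to the
#' baseline group is `2^-(dCt - mean(dCt_baseline))`, so the baseline
#' group's mean sample has fold change 1 by construction.
#'
#' @param ct A `ct_table` (long: `sample, group, gene, replicate, ct,
#'   ct_ref`).
#' @param baseline_group Baseline group label (default `"NA"`, the
#'   wild-type feather class).
#' @return Data frame `sample, group, gene, dct, fold_change`.
#' @export
relative_expression <- function(ct, baseline_group = "NA") {
  key <- interaction(ct$sample, ct$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(g)
    data.frame(sample = g$sample[1], group = g$group[1], gene = g$gene[1],
               dct = mean(g$ct) - mean(g$ct_ref))))
  out <- do.call(rbind, lapply(split(agg, agg$gene), function(g) {
    base <- g$dct[g$group == baseline_group]
    if (!length(base))
      stop("gene ", g$gene[1], " has no samples in baseline group '",
           baseline_group, "'")
    g$fold_change <- 2^(-(g$dct - mean(base)))
    g
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene group comparison: ANOVA, Tukey HSD, compact letter display
#'
#' One-way ANOVA on dCt (the log2 expression scale, where replicate
#' variance is closest to homogeneous) followed by Tukey's HSD over all
#' group pairs; groups are labelled by an insert-and-absorb compact letter
#' display so that groups sharing a letter are not significantly different
#' at `alpha`. Groups with fewer than 2 samples are excluded with a
#' warning.
#'
#' @param ct A `ct_table`.
#' @param alpha Significance level (default 0.05).
#' @return Named list per gene: `f`, `anova_p`, `tukey` (data frame of
#'   pairwise comparisons), `letters` (named character vector).
#' @export
group_comparison <- function(ct, alpha = 0.05) {
  key <- interaction(ct$sample, ct$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(g)
    data.frame(sample = g$sample[1], group = g$group[1], gene = g$gene[1],
               dct = mean(g$ct) - mean(g$ct_ref))))
  lapply(split(agg, agg$gene), function(g) {
    sizes <- table(g$group)
    small <- names(sizes)[sizes < 2L]
    if (length(small)) {
      warning("gene ", g$gene[1], ": excluding group(s) with < 2 samples: ",
              paste(small, collapse = ", "))
      g <- g[!g$group %in% small, , drop = FALSE]
    }
    if (length(unique(g$group)) < 2L)
      stop("gene ", g$gene[1], ": need >= 2 groups with >= 2 samples")
    g$group <- factor(g$group)
    fit <- stats::aov(dct ~ group, data = g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    tkdf <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL)
    sig <- tkdf[tkdf$p_adj < alpha, "pair"]
    sig_pairs <- strsplit(sig, "-", fixed = TRUE)
    list(f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1], tukey = tkdf,
         letters = letter_display(levels(g$group), sig_pairs))
  })
}

# insert-and-absorb compact letter display: start from one letter covering
# all groups; for each significantly different pair, split every column
# containing both; absorb columns contained in another
letter_display <- function(groups, sig_pairs) {
  cols <- list(groups)
  for (pr in sig_pairs) {
    for (ci in rev(seq_along(cols))) {
      col <- cols[[ci]]
      if (all(pr %in% col)) {
        cols[[ci]] <- setdiff(col, pr[1])
        cols[[length(cols) + 1L]] <- setdiff(col, pr[2])
      }
    }
    # absorb duplicates / subsets
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols))
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b))
        keep[a] <- FALSE
    cols <- cols[keep]
  }
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols))
    for (g in cols[[ci]]) lab[g] <- paste0(lab[g], letters[ci])
  lab
}
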