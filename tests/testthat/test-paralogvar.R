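# compact builder for hand-specified AD tables
mk_vt <- function(ad_by_site, alleles, pos = NULL, scaffold = "sc1") {
  samples <- rownames(ad_by_site[[1]])
  n <- length(ad_by_site)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = n)
  dp <- do.call(rbind, lapply(ad_by_site, rowSums))
  variant_table(rep(scaffold, n), pos, alleles, ad_by_site,
                matrix(as.integer(dp), n, length(samples),
                       dimnames = list(NULL, samples)), samples)
}

test_that("the 4% allelic-fraction filter is strictly greater-than", {
  samples <- c("c1", "c2")
  ad <- matrix(c(93L, 7L, 96L, 4L), 2, 2, byrow = TRUE,
               dimnames = list(samples, NULL))
  vt <- mk_vt(list(ad), list(c("A", "T")))
  ret <- filter_allelic_fraction(vt)
  # 7/100 = 0.07 > 0.04 retained; 4/100 = 0.04 is not (> is strict)
  expect_equal(ret$sample, "c1")
  expect_equal(ret$frac, 0.07)
  # AD 0 removed; DP 0 sample skipped silently
  ad0 <- matrix(c(100L, 0L, 0L, 0L), 2, 2, byrow = TRUE,
                dimnames = list(samples, NULL))
  expect_equal(nrow(filter_allelic_fraction(mk_vt(list(ad0),
                                                  list(c("A", "T"))))), 0L)
  # monotone: raising min_frac never grows the retained set
  set.seed(5)
  cfg <- paralog_config()
  co <- simulate_cohort(cfg)
  vts <- simulate_allele_depths(co, cfg, seed = 15)
  n_at <- vapply(c(0.02, 0.04, 0.08, 0.2), function(f)
    nrow(filter_allelic_fraction(vts, min_frac = f)), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("biallelic private alleles require zero retained controls", {
  samples <- c("c1", "c2", "c3", "c4", "c5", "k1", "k2")
  cases <- samples[1:5]; controls <- samples[6:7]
  mk <- function(ctrl_ad) {
    ad <- rbind(matrix(rep(c(90L, 10L), 5), 5, 2, byrow = TRUE),
                matrix(ctrl_ad, 2, 2, byrow = TRUE))
    rownames(ad) <- samples
    mk_vt(list(ad), list(c("A", "G")))
  }
  ret_priv <- filter_allelic_fraction(mk(c(100L, 0L)))
  out <- biallelic_private_alleles(ret_priv, cases, controls)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_cases_retained, 5L)
  # allele retained in both cohorts is excluded
  ret_shared <- filter_allelic_fraction(mk(c(90L, 10L)))
  expect_equal(nrow(biallelic_private_alleles(ret_shared, cases, controls)),
               0L)
  # empty retained set
  empty <- filter_allelic_fraction(mk(c(100L, 0L)), min_frac = 0.5)
  expect_equal(nrow(biallelic_private_alleles(empty, cases, controls)), 0L)
})

test_that("recurrence scan counts >=1-read presence across cases", {
  cases <- sprintf("c%02d", 1:10)
  # multiallelic site: allele G present (>= 1 read) in exactly 3 cases,
  # allele T in 2
  ad <- matrix(0L, 10, 3, dimnames = list(cases, NULL))
  ad[, 1] <- 50L
  ad[1:3, 2] <- 1L
  ad[4:5, 3] <- 9L
  vt <- mk_vt(list(ad), list(c("A", "G", "T")))
  out <- recurrence_scan(vt, cases, min_cases = 3)
  expect_equal(out$allele, "G")
  expect_equal(out$n_cases_present, 3L)
  pres <- attr(out, "presence")
  expect_true(all(pres %in% 0:1))
  expect_equal(unname(rowSums(pres)), c(3L, 2L))
  # all-zero matrix: empty
  ad0 <- ad; ad0[, 2:3] <- 0L
  expect_equal(nrow(recurrence_scan(mk_vt(list(ad0),
                                          list(c("A", "G", "T"))), cases)),
               0L)
  # monotone in min_cases
  expect_gte(nrow(recurrence_scan(vt, cases, min_cases = 1)),
             nrow(recurrence_scan(vt, cases, min_cases = 3)))
})

test_that("control cross-check removes alleles with any control read", {
  all_s <- c(sprintf("c%02d", 1:10), "k1", "k2")
  ad <- matrix(0L, 12, 3, dimnames = list(all_s, NULL))
  ad[, 1] <- 50L
  ad[1:4, 2] <- 5L          # case-only allele G
  ad[1:4, 3] <- 5L; ad[11, 3] <- 1L   # allele T leaks into control k1
  vt <- mk_vt(list(ad), list(c("A", "G", "T")))
  cand <- recurrence_scan(vt, all_s[1:10], min_cases = 3)
  expect_equal(sort(cand$allele), c("G", "T"))
  ok <- control_cross_check(cand, vt, c("k1", "k2"))
  expect_equal(ok$allele, "G")
  expect_equal(ok$verdict, "case-specific")
})

test_that("the null paralog scan is empty, mirroring a negative search", {
  cfg <- paralog_config(n_private_snvs = 0L)
  co <- simulate_cohort(cfg)
  vt <- simulate_allele_depths(co, cfg, seed = 101)
  out <- paralog_scan(vt, co$samples, region = cfg$outer)
  expect_equal(nrow(out), 0L)
})

test_that("planted copy-private alleles are recovered when truly absent
           from control reads", {
  cfg <- paralog_config()
  co <- simulate_cohort(cfg)
  cases <- co$samples$id[co$samples$phenotype == "Almond"]
  controls <- setdiff(co$samples$id, cases)
  hits <- 0L; trials <- 0L
  for (k in 1:100) {
    vt <- simulate_allele_depths(co, cfg, seed = 20000 + k)
    planted <- attr(vt, "planted")
    out <- paralog_scan(vt, co$samples, region = cfg$outer)
    # score each planted allele with zero reads in every control sample
    for (r in seq_len(nrow(planted))) {
      i <- which(vt$pos == planted$pos[r])
      a <- match(planted$allele[r], vt$alleles[[i]])
      if (sum(vt$ad[[i]][controls, a], na.rm = TRUE) > 0L) next
      trials <- trials + 1L
      if (any(out$pos == planted$pos[r] & out$allele == planted$allele[r]))
        hits <- hits + 1L
    }
  }
  expect_gt(trials, 50L)
  expect_gte(hits / trials, 0.95)
})

test_that("error-only alleles rarely pass the 4% filter", {
  cfg <- paralog_config()
  co <- simulate_cohort(cfg)
  controls <- co$samples$id[co$samples$phenotype == "non-Almond"]
  # controls never carry the planted allele, so their reads of it are pure
  # sequencing error; count control sample-sites where it clears 4%
  n_pass <- 0L; n_pairs <- 0L
  for (k in 1:10) {
    vt <- simulate_allele_depths(co, cfg, n_background = 0L, n_multi = 0L,
                                 seed = 3000 + k)
    planted <- attr(vt, "planted")
    ret <- filter_allelic_fraction(vt, samples = controls)
    key <- paste(ret$pos, ret$allele)
    n_pass <- n_pass + sum(key %in% paste(planted$pos, planted$allele))
    n_pairs <- n_pairs + nrow(planted) * length(controls)
  }
  expect_lt(n_pass / n_pairs, 0.01)
})

test_that("scan output is invariant to sample order", {
  cfg <- paralog_config()
  co <- simulate_cohort(cfg)
  vt <- simulate_allele_depths(co, cfg, seed = 55)
  out1 <- paralog_scan(vt, co$samples, region = cfg$outer)
  perm <- sample(nrow(co$samples))
  out2 <- paralog_scan(vt, co$samples[perm, ], region = cfg$outer)
  expect_equal(out1, out2)
})
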