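test_that("cohort truths follow sex ploidy and the allele series", {
  cfg <- test_config()
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$samples), 121L)
  # hemizygous case female: one Z with the canonical expansion
  f <- co$truth[["case_01"]]
  expect_equal(f$outer_copies, 7L)
  expect_equal(f$inner_copies, 14L)
  # wild-type male: 1 inner copy per Z, 2 in total
  m <- co$truth[["ctrl_056"]]
  expect_equal(sum(m$inner_copies), 2L)
  # heterozygous case male: 14 + 1
  hm <- co$truth[["case_11"]]
  expect_equal(sort(hm$inner_copies), c(1L, 14L))
  # homozygous case male: 28 inner copies in total
  hom <- simulate_cohort(cfg, homozygous_ids = "case_11")
  expect_equal(sum(hom$truth[["case_11"]]$inner_copies), 28L)
  expect_error(sim_config(n_case_female = 0, n_case_male = 0), NA)
  expect_error(simulate_cohort(sim_config(n_case_female = 0L,
                                          n_case_male = 0L)),
               "non-empty")
})

test_that("truth invariants hold: nesting, copy ordering, validation", {
  cfg <- test_config()
  expect_error(cnv_truth(cfg, outer_copies = 0L, inner_copies = 1L), ">= 1")
  expect_error(cnv_truth(cfg, outer_copies = 3L, inner_copies = 2L),
               ">= outer")
  expect_error(sim_config(inner = c(5190000, 5600000)), "nested")
  expect_error(sim_config(coverage = 0), "coverage")
})

test_that("depth simulation has the right flat and stepped expectations", {
  cfg <- test_config()
  wt <- cnv_truth(cfg, 1L, 1L)
  alm <- cnv_truth(cfg, 7L, 14L)
  # noiseless: exact step profile
  tr0 <- simulate_depth(alm, cfg, noise = FALSE)
  mid <- (tr0$start + tr0$end) / 2
  expect_equal(unique(tr0$depth[mid < cfg$outer$start]), 30)
  expect_equal(unique(tr0$depth[mid > cfg$outer$start + 200 &
                                  mid < cfg$inner$start - 200]), 210)
  expect_equal(unique(tr0$depth[mid > cfg$inner$start + 200 &
                                  mid < cfg$inner$end - 200]), 420)
  # depth ratio inner : outer : flank = 14 : 7 : 1
  expect_equal(c(420, 210, 30) / 30, c(14, 7, 1))
  # wild-type female at 30x: long-run mean ~ 30
  tr <- simulate_depth(wt, cfg, seed = 5)
  expect_lt(abs(mean(tr$depth) - 30), 3 * sqrt(30 / nrow(tr)))
  # fixed seed => bit-identical output
  expect_identical(simulate_depth(alm, cfg, seed = 9),
                   simulate_depth(alm, cfg, seed = 9))
})

test_that("clip piles mark junctions with counts ordered by junction copies", {
  cfg <- test_config(clip_bg_rate = 0)
  # single-copy genome: no junction piles at all
  expect_equal(nrow(simulate_clip_piles(cnv_truth(cfg, 1L, 1L), cfg,
                                        seed = 2)), 0L)
  alm <- cnv_truth(cfg, 7L, 14L)
  piles <- simulate_clip_piles(alm, cfg, seed = 2)
  expect_setequal(piles$pos, unname(alm$breakpoints))
  # expectation over many draws: inner junction piles exceed outer
  set.seed(31)
  inner_mean <- mean(replicate(1000, {
    p <- simulate_clip_piles(alm, cfg)
    p$count[p$pos == alm$breakpoints[["inner_left"]]]
  }))
  outer_mean <- mean(replicate(1000, {
    p <- simulate_clip_piles(alm, cfg)
    p$count[p$pos == alm$breakpoints[["outer_left"]]]
  }))
  # means ~ coverage * (i - o) = 210 vs coverage * (o - 1) = 180
  expect_lt(abs(inner_mean - 210), 3 * sqrt(210 / 1000) * 10)
  expect_lt(abs(outer_mean - 180), 3 * sqrt(180 / 1000) * 10)
  expect_gt(inner_mean, outer_mean)
})

test_that("allelic fractions of copy-private variants scale as 1/copies", {
  cfg <- paralog_config(error_rate = 0, n_private_snvs = 2L)
  co <- simulate_cohort(cfg)
  vt <- simulate_allele_depths(co, cfg, n_background = 0L, n_multi = 0L,
                               seed = 7)
  planted <- attr(vt, "planted")
  cases <- co$samples$id[co$samples$phenotype == "Almond"]
  fr <- c()
  for (r in seq_len(nrow(planted))) {
    i <- which(vt$pos == planted$pos[r])
    a <- match(planted$allele[r], vt$alleles[[i]])
    fr <- c(fr, vt$ad[[i]][cases, a] / vt$dp[i, cases])
  }
  # hemizygous females with 14 inner copies: expected fraction 1/14 ~ 7%
  expect_lt(abs(mean(fr) - 1 / 14), 0.01)
  # controls carry no reads of the planted allele when error-free
  ctrl <- setdiff(co$samples$id, cases)
  for (r in seq_len(nrow(planted))) {
    i <- which(vt$pos == planted$pos[r])
    a <- match(planted$allele[r], vt$alleles[[i]])
    expect_true(all(vt$ad[[i]][ctrl, a] == 0L))
  }
})

test_that("error-only alleles have expectation DP * rate and fixed variants ~1", {
  # expectation arithmetic: rate 0.005 at DP 200 -> expected AD 1 split
  # over three alternate bases
  expect_equal(200 * 0.005, 1)
  cfg <- paralog_config(error_rate = 0.005, n_private_snvs = 0L)
  co <- simulate_cohort(cfg)
  vt <- simulate_allele_depths(co, cfg, n_background = 20L, n_multi = 0L,
                               seed = 8)
  # a background allele drawn at frequency ~0.5 appears at fraction ~ its
  # copy share; sanity: all fractions within [0, 1]
  fr <- unlist(lapply(seq_len(n_sites(vt)), function(i)
    vt$ad[[i]][, -1, drop = FALSE] / vt$dp[i, ]))
  expect_true(all(fr >= 0 & fr <= 1, na.rm = TRUE))
})

test_that("assay and expression simulators invert exactly at zero noise", {
  cfg <- test_config(assay_sd = 0, expr_sd = 0)
  co <- simulate_cohort(cfg)
  at <- simulate_assay(co, cfg, seed = 3)
  est <- quantify_copies(at)
  # zero-noise round trip recovers every integer truth exactly
  expect_equal(est$cn_integer[match(co$samples$id, est$sample)],
               co$samples$total_inner_truth)
  # CN 14 female vs CN 1 calibrator: ddCt = -log2(14)
  f <- est[est$sample == "case_01", ]
  expect_equal(f$ddct, -log2(14))
  expect_error(simulate_assay(co, cfg, calibrator = "nope"), "calibrator")
  # expression: a -log2(40) group effect comes back as 40-fold
  groups <- data.frame(sample = sprintf("s%d", 1:8),
                       group = rep(c("NA", "DA"), each = 4))
  ctt <- simulate_expression(groups, list(g1 = c(DA = -log2(40))), cfg,
                             seed = 4)
  re <- relative_expression(ctt)
  expect_equal(unique(re$fold_change[re$group == "DA"]), 40)
  expect_equal(unique(re$fold_change[re$group == "NA"]), 1)
})

test_that("simulators are bit-reproducible and write what core_io reads", {
  cfg <- paralog_config(coord_offset = 5160000L, scaffold_length = 120000L)
  co <- simulate_cohort(cfg)
  a <- simulate_allele_depths(co, cfg, seed = 12)
  b <- simulate_allele_depths(co, cfg, seed = 12)
  expect_identical(a, b)
  # full write/read loop: VCF + sample sheet + depth table + truth JSON
  dir <- withr::local_tempdir()
  write_variant_table(a, file.path(dir, "sim.vcf"))
  back <- read_variant_table(file.path(dir, "sim.vcf"))
  expect_equal(back$pos, a$pos)
  expect_equal(unname(back$dp), unname(a$dp))
  write_sample_sheet(co$samples, file.path(dir, "samples.csv"))
  sh <- read_sample_sheet(file.path(dir, "samples.csv"))
  expect_equal(sh$id, co$samples$id)
  expect_equal(sh$z_baseline, co$samples$z_baseline)
  tr <- simulate_depth(co$truth[["case_01"]], cfg, seed = 1)
  write_depth_table(list(case_01 = tr), file.path(dir, "depth.tsv"))
  tr2 <- read_depth_table(file.path(dir, "depth.tsv"), window = cfg$window)
  expect_equal(tr2$case_01$depth, tr$depth)
  write_truth(co, file.path(dir, "truth.json"))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(tj$case_01$inner_copies), 14L)
})
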