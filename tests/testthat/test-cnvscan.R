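test_that("normalization fixes the control median at 1 and is idempotent", {
  cfg <- test_config()
  ctrl <- control_interval(cfg)
  wt <- cnv_truth(cfg, 1L, 1L)
  tr <- simulate_depth(wt, cfg, noise = FALSE)
  nt <- normalize_depth(tr, ctrl)
  expect_true(all(nt$norm == 1))
  # CNV windows at 7x control normalize to 7
  alm <- cnv_truth(cfg, 7L, 14L)
  nt2 <- normalize_depth(simulate_depth(alm, cfg, noise = FALSE), ctrl)
  mid <- (nt2$start + nt2$end) / 2
  expect_equal(unique(nt2$norm[mid > cfg$outer$start + 200 &
                                 mid < cfg$inner$start - 200]), 7)
  # idempotence and exact control median 1
  nt3 <- normalize_depth(nt2, ctrl)
  expect_equal(nt3$norm, nt2$norm)
  ctrl_mid <- in_ctrl <- mid >= ctrl$start & mid <= ctrl$end
  expect_equal(median(nt2$norm[in_ctrl]), 1)
  # hand-computed ratios on a 10-window fixture
  t10 <- depth_track("sc1", seq(1, 901, by = 100), seq(100, 1000, by = 100),
                     c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100), "s", 100)
  n10 <- normalize_depth(t10, genomic_interval("sc1", 1, 1000))
  expect_equal(n10$norm, c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100) / 55)
  # uncovered control region errors
  z <- depth_track("sc1", seq(1, 901, by = 100), seq(100, 1000, by = 100),
                   rep(0, 10), "s", 100)
  expect_error(normalize_depth(z, genomic_interval("sc1", 1, 1000)),
               "uncovered control")
  expect_error(normalize_depth(t10, genomic_interval("sc1", 1, 300)),
               ">= 10 windows")
})

test_that("integer copy number rounds the median with sex-aware baselines", {
  cfg <- test_config()
  ctrl <- control_interval(cfg)
  # female with median normalized ~7 over the outer shoulders -> CN 7
  alm <- cnv_truth(cfg, 7L, 14L)
  nt <- normalize_depth(simulate_depth(alm, cfg, seed = 61), ctrl)
  expect_equal(copy_number(nt, cfg$outer, baseline = 1,
                           exclude = cfg$inner)$total, 7L)
  expect_equal(copy_number(nt, cfg$inner, baseline = 1)$total, 14L)
  # male non-CNV region: median ~1 -> 1 per chromosome, 2 total
  wt_m <- cnv_truth(cfg, c(1L, 1L), c(1L, 1L))
  ntm <- normalize_depth(simulate_depth(wt_m, cfg, seed = 62), ctrl)
  cn <- copy_number(ntm, cfg$inner, baseline = 2)
  expect_equal(cn$total, 2L)
  expect_equal(cn$per_chromosome, 1)
  expect_error(copy_number(ntm, genomic_interval(cfg$scaffold, 1, 250),
                           baseline = 2), "fewer than 5")
})

test_that("segmentation is exact on noiseless steps and robust to noise", {
  cfg <- test_config()
  ctrl <- control_interval(cfg)
  alm <- cnv_truth(cfg, 7L, 14L)
  # flat track: a single segment
  wt <- normalize_depth(simulate_depth(cnv_truth(cfg, 1L, 1L), cfg,
                                       seed = 71), ctrl)
  expect_equal(nrow(segment_track(wt)), 1L)
  # noiseless 1 -> 7 -> 14 -> 7 -> 1: five segments at window-exact bounds
  nt0 <- normalize_depth(simulate_depth(alm, cfg, noise = FALSE), ctrl)
  s0 <- segment_track(nt0)
  expect_equal(nrow(s0), 5L)
  expect_equal(s0$level, c(1, 7, 14, 7, 1))
  win <- cfg$window
  expect_lte(abs(s0$start[2] - alm$breakpoints[["outer_left"]]), win)
  expect_lte(abs(s0$start[3] - alm$breakpoints[["inner_left"]]), win)
  expect_lte(abs(s0$end[3] - alm$breakpoints[["inner_right"]]), win)
  expect_lte(abs(s0$end[4] - alm$breakpoints[["outer_right"]]), win)
  # Poisson noise at 30x, 100 seeded replicates: boundaries within +/- 2
  # windows of truth
  miss <- 0L
  for (k in 1:100) {
    nt <- normalize_depth(simulate_depth(alm, cfg, seed = 7000 + k), ctrl)
    s <- segment_track(nt)
    ok <- nrow(s) == 5 &&
      abs(s$start[2] - alm$breakpoints[["outer_left"]]) <= 2 * win &&
      abs(s$start[3] - alm$breakpoints[["inner_left"]]) <= 2 * win &&
      abs(s$end[3] - alm$breakpoints[["inner_right"]]) <= 2 * win &&
      abs(s$end[4] - alm$breakpoints[["outer_right"]]) <= 2 * win
    if (!ok) miss <- miss + 1L
  }
  expect_lte(miss, 5L)
})

test_that("breakpoint detection thresholds, merges and recovers truth", {
  piles <- data.frame(scaffold = "sc1", pos = c(100L, 500L),
                      side = c("left", "right"), count = c(5L, 2L))
  bp <- detect_breakpoints(piles, min_support = 3)
  expect_equal(bp$pos, 100L)
  # background 1-read clips only: empty
  bg <- data.frame(scaffold = "sc1", pos = c(10L, 99L, 731L),
                   side = "left", count = 1L)
  expect_equal(nrow(detect_breakpoints(bg)), 0L)
  # merge within 5 bp keeps the max-count position
  close <- data.frame(scaffold = "sc1", pos = c(100L, 103L, 200L),
                      side = "left", count = c(4L, 9L, 3L))
  bp <- detect_breakpoints(close)
  expect_equal(bp$pos, c(103L, 200L))
  expect_equal(bp$count[1], 9L)
  # simulated truth: all four breakpoints at exact simulated positions
  cfg <- test_config()
  alm <- cnv_truth(cfg, 7L, 14L)
  got <- detect_breakpoints(simulate_clip_piles(alm, cfg, seed = 81))
  expect_true(all(unname(alm$breakpoints) %in% got$pos))
})

test_that("call assembly pairs depth steps with breakpoints and flags gaps", {
  cfg <- test_config()
  ctrl <- control_interval(cfg)
  alm <- cnv_truth(cfg, 7L, 14L)
  nt <- normalize_depth(simulate_depth(alm, cfg, seed = 91), ctrl)
  segs <- segment_track(nt)
  bp <- detect_breakpoints(simulate_clip_piles(alm, cfg, seed = 92))
  call <- assemble_call(segs, bp, baseline = 1)
  expect_equal(call$outer_cn, 7)
  expect_equal(call$inner_cn, 14)
  expect_equal(unname(call$breakpoints), unname(alm$breakpoints))
  expect_length(call$flags, 0L)
  # inner-only duplication: outer CN 1, flagged
  io <- cnv_truth(cfg, 1L, 2L)
  nt_io <- normalize_depth(simulate_depth(io, cfg, seed = 93), ctrl)
  call_io <- assemble_call(segment_track(nt_io),
                           detect_breakpoints(simulate_clip_piles(io, cfg,
                                                                  seed = 94)),
                           baseline = 1)
  expect_equal(call_io$outer_cn, 1)
  expect_equal(call_io$inner_cn, 2)
  expect_true("inner-only" %in% call_io$flags)
  # wild type: no call
  wt <- normalize_depth(simulate_depth(cnv_truth(cfg, 1L, 1L), cfg,
                                       seed = 95), ctrl)
  expect_null(assemble_call(segment_track(wt), bp, baseline = 1))
  # depth step without nearby breakpoint support: flagged depth-only
  call_d <- assemble_call(segs, bp[0, ], baseline = 1)
  expect_true("depth-only" %in% call_d$flags)
})

test_that("junction counts match exhaustive arrangement enumeration", {
  cfg <- test_config()
  for (o in 1:10) for (r in 1:4) {
    call <- list(outer_cn = o, inner_cn = o * r)
    st <- infer_structure(call)
    expect_equal(st$junctions, oracle_junctions(o, r))
    # arrangement invariant: S1 (S2 x r) S3 repeated o times
    expect_equal(length(st$arrangement), o * (r + 2))
  }
  # canonical case
  st <- infer_structure(list(outer_cn = 7, inner_cn = 14))
  expect_equal(unname(st$junctions), c(7L, 7L, 7L, 6L))
  # wild type: no novel junctions
  st0 <- infer_structure(list(outer_cn = 1, inner_cn = 1))
  expect_equal(st0$arrangement, c("S1", "S2", "S3"))
  expect_equal(st0$junctions[["j22"]], 0L)
  expect_equal(st0$junctions[["j31"]], 0L)
  # o=1, i=2: one 2/2 junction, zero 3/1
  st12 <- infer_structure(list(outer_cn = 1, inner_cn = 2))
  expect_equal(st12$junctions[["j22"]], 1L)
  expect_equal(st12$junctions[["j31"]], 0L)
  # non-divisible structures rejected with proposals
  expect_error(infer_structure(list(outer_cn = 3, inner_cn = 7)),
               "not divisible.*6 or 9")
})

test_that("gene effects follow placement and junction counts", {
  cfg <- test_config()
  genes <- example_gene_models(cfg)
  call <- list(outer = cfg$outer, inner = cfg$inner,
               outer_cn = 7, inner_cn = 14)
  st <- infer_structure(call)
  eff <- predict_gene_effects(st, genes, call)
  get <- function(g) eff[eff$gene == g, ]
  # gene inside the inner segment: amplified to 14 copies per chromosome
  expect_equal(get("Mlana")$effect, "amplified_full")
  expect_equal(get("Mlana")$copies_per_chromosome, 14)
  # inner-boundary straddler: o full copies (2/3 junctions), o(r-1)
  # truncated (2/2), with the enumeration note attached
  expect_equal(get("Slc16a13")$effect, "truncated_at_junction")
  expect_equal(get("Slc16a13")$copies_per_chromosome, 7)
  expect_equal(get("Slc16a13")$truncated_copies, 7)
  expect_match(get("Slc16a13")$note, "enumeration")
  # fusion pair across the outer breakpoints: o - 1 = 6 fusion copies
  fus <- attr(eff, "fusion")
  expect_equal(nrow(fus), 1L)
  expect_equal(fus$gene_5prime, "Ermp1")
  expect_equal(fus$gene_3prime, "Kiaa2026")
  expect_equal(fus$copies, 6L)
  # outside gene unchanged
  expect_equal(get("Ric1")$effect, "unchanged")
  # wild-type structure: nothing amplified, no fusion
  wt_call <- list(outer = cfg$outer, inner = cfg$inner,
                  outer_cn = 1, inner_cn = 1)
  eff0 <- predict_gene_effects(infer_structure(wt_call), genes, wt_call)
  expect_equal(nrow(attr(eff0, "fusion")), 0L)
  expect_equal(eff0$copies_per_chromosome[eff0$gene == "Mlana"], 1)
  # inside-S2 total copies equal inner CN for every structure
  for (o in c(1, 2, 7)) for (r in 1:3) {
    cl <- list(outer = cfg$outer, inner = cfg$inner,
               outer_cn = o, inner_cn = o * r)
    ef <- predict_gene_effects(infer_structure(cl), genes, cl)
    expect_equal(ef$copies_per_chromosome[ef$gene == "Mlana"], o * r)
  }
  # a gene on another scaffold is a hard error
  off <- gene_model("Off", "other_scaffold", "+",
                    data.frame(start = 1, end = 10))
  expect_error(predict_gene_effects(st, list(off), call), "scaffold")
})
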