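test_that("main effect reproduces brute-force Welch SE, pooled F and p on a hand fixture", {
  # six participants, nf enhanced for the first three
  recs <- make_records(
    make_record(id = "1", nf = 1L, baseline_pwac = 40, followup_pwac = 18),
    make_record(id = "2", nf = 1L, baseline_pwac = 35, followup_pwac = 25),
    make_record(id = "3", nf = 1L, baseline_pwac = 50, followup_pwac = 31),
    make_record(id = "4", nf = 0L, baseline_pwac = 42, followup_pwac = 40),
    make_record(id = "5", nf = 0L, baseline_pwac = 38, followup_pwac = 30),
    make_record(id = "6", nf = 0L, baseline_pwac = 45, followup_pwac = 44))
  aset <- change_scores(recs, "pwac")
  res <- main_effect(aset, "nf")

  va <- aset$values[1:3]   # enhanced changes: -22, -10, -19
  vb <- aset$values[4:6]   # minimal changes: -2, -8, -1
  expect_equal(res$effect$mean_a, mean(va))
  expect_equal(res$effect$mean_b, mean(vb))
  # predicted direction: minimal change minus enhanced change, positive here
  expect_equal(res$effect$mean_diff, mean(vb) - mean(va))
  expect_gt(res$effect$mean_diff, 0)

  welch <- t.test(vb, va, var.equal = FALSE)
  pooled <- t.test(vb, va, var.equal = TRUE)
  expect_equal(res$effect$se, welch$stderr, tolerance = 1e-12)
  expect_equal(res$F, unname(pooled$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, pooled$p.value, tolerance = 1e-12)
})

test_that("identical groups give a zero difference and zero F", {
  recs <- make_records(
    make_record(id = "1", ap = 1L, baseline_pwac = 40, followup_pwac = 30),
    make_record(id = "2", ap = 1L, baseline_pwac = 30, followup_pwac = 25),
    make_record(id = "3", ap = 0L, baseline_pwac = 50, followup_pwac = 40),
    make_record(id = "4", ap = 0L, baseline_pwac = 20, followup_pwac = 15))
  aset <- change_scores(recs, "pwac")
  res <- main_effect(aset, "ap")
  expect_equal(res$effect$mean_diff, 0)
  expect_equal(res$F, 0)
})

test_that("contrast membership counts follow the 2^5 design arithmetic", {
  f <- fixture_small(5)   # 64 participants, every cell exactly twice
  aset <- change_scores(f, "pwac")
  m <- main_effect(aset, "smf")
  expect_equal(c(m$effect$n_a, m$effect$n_b), c(32L, 32L))
  i <- interaction_effect(aset, c("nf", "ic"))
  expect_equal(c(i$effect$n_a, i$effect$n_b), c(16L, 16L))  # 1/4 each side
  s4 <- synergy_effect(aset, c("nf", "cbr", "smf", "ap"))
  expect_equal(c(s4$effect$n_a, s4$effect$n_b), c(4L, 4L))  # 1/16 each side
  s5 <- synergy_effect(aset, names(trial_modules()))
  expect_equal(c(s5$effect$n_a, s5$effect$n_b), c(2L, 2L))  # 1/32 each side

  # the ten pair contrasts use disjoint, reproducible cells
  pairs <- combn(names(trial_modules()), 2, simplify = FALSE)
  counts <- vapply(pairs, function(p) {
    r <- interaction_effect(aset, p)
    r$effect$n_a + r$effect$n_b
  }, numeric(1))
  expect_true(all(counts == 32))
})

test_that("interaction excludes mixed cells", {
  f <- fixture_small(5)
  aset <- change_scores(f, "pwac")
  i <- interaction_effect(aset, c("cbr", "ap"))
  both_on <- f$mod_cbr == 1 & f$mod_ap == 1
  both_off <- f$mod_cbr == 0 & f$mod_ap == 0
  expect_equal(i$effect$n_a, sum(both_on))
  expect_equal(i$effect$n_b, sum(both_off))
  expect_equal(i$effect$mean_a, mean(aset$values[both_on]))
  expect_equal(i$effect$mean_b, mean(aset$values[both_off]))
})

test_that("degenerate contrasts are rejected with informative errors", {
  f <- fixture_small(5)
  aset <- change_scores(f, "pwac")
  expect_error(contrast_spec("main", c("nf", "ic")), "exactly 1")
  expect_error(contrast_spec("interaction", "nf"), "exactly 2")
  expect_error(contrast_spec("synergy", "nf"), "2-5")
  expect_error(contrast_spec("main", "xx"), "unknown module")
  # empty cell: all-enhanced side absent
  sub <- f[!(f$mod_nf == 1 & f$mod_cbr == 1), ]
  expect_error(synergy_effect(change_scores(sub, "pwac"), c("nf", "cbr")),
               "empty cell")
})

test_that("a single-module effect is recovered and the SE shrinks as 1/sqrt(n)", {
  cfg <- sim_config(n_original = 10000L, n_extended = 0L,
                    response_rate_original = 1,
                    module_effects = c(smf = -5), seed = 101L)
  recs <- simulate_trial(cfg)
  aset <- change_scores(recs, "pwac")
  res <- main_effect(aset, "smf")
  mc_se <- res$effect$se
  # greater reduction under enhanced -> positive predicted-direction diff ~ 5
  expect_lt(abs(res$effect$mean_diff - 5), 3 * mc_se)

  small <- simulate_trial(sim_config(n_original = 2500L, n_extended = 0L,
                                     response_rate_original = 1, seed = 102L))
  se_small <- main_effect(change_scores(small, "pwac"), "smf")$effect$se
  expect_gt(mc_se, 0)
  expect_equal(se_small / mc_se, 2, tolerance = 0.15)  # 1/sqrt(n) scaling
})

test_that("under a balanced null the pooled-F p-values are uniform", {
  set.seed(99)
  pvals <- replicate(400, {
    recs <- fixture_small(sample.int(1e6, 1))
    main_effect(change_scores(recs, "pwac"), "nf")$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(pvals < 0.5), 0.4)
})

test_that("report tables mirror the published column layout and rounding", {
  f <- fixture_small(5)
  aset <- change_scores(f, "pwac")
  results <- lapply(names(trial_modules()), function(m) main_effect(aset, m))
  tab <- report_table(results, c(5, 3, 0.5))
  expect_equal(nrow(tab), 5)
  expect_true(all(c("mean_enhanced", "sd_enhanced", "mean_minimal",
                    "sd_minimal", "F", "p", "bf_h0_5", "bf_h0_3",
                    "bf_h0_0.5", "category") %in% names(tab)))
  expect_equal(tab$contrast[1], "Normative Feedback")
  full <- report_table(results, c(5, 3, 0.5), rounded = FALSE)
  expect_equal(tab$bf_h0_5, round(full$bf_h0_5, 2))
  expect_equal(tab$F, round(full$F, 3))
})
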