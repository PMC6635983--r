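test_that("permuted-block allocation balances all 32 cells and every margin", {
  recs <- simulate_trial(sim_config(n_original = 320L, n_extended = 0L,
                                    seed = 8L))
  cells <- interaction(recs[paste0("mod_", names(trial_modules()))],
                       drop = FALSE)
  expect_equal(as.integer(table(cells)), rep(10L, 32L))  # 320 / 32 per cell
  for (col in paste0("mod_", names(trial_modules())))
    expect_equal(mean(recs[[col]]), 0.5)  # enhanced fraction exact

  # balance holds at every block boundary, not just the end
  first_block <- recs[1:32, ]
  cells1 <- interaction(first_block[paste0("mod_", names(trial_modules()))],
                        drop = FALSE)
  expect_equal(as.integer(table(cells1)), rep(1L, 32L))
})

test_that("the generator is deterministic under a fixed seed and varies across seeds", {
  a <- simulate_trial(sim_config(n_original = 128L, n_extended = 64L, seed = 5L))
  b <- simulate_trial(sim_config(n_original = 128L, n_extended = 64L, seed = 5L))
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(a, p1, header_comment = "seed: 5")
  write_trial_csv(b, p2, header_comment = "seed: 5")
  expect_identical(readLines(p1), readLines(p2))

  c_ <- simulate_trial(sim_config(n_original = 128L, n_extended = 64L, seed = 6L))
  expect_false(identical(a$mod_nf, c_$mod_nf) &&
                 identical(a$baseline_pwac, c_$baseline_pwac))
})

test_that("simulated baselines match the target moments despite truncation", {
  big <- simulate_trial(sim_config(n_original = 100000L, n_extended = 0L,
                                   seed = 2L))
  n <- nrow(big)
  # consumption: target mean 39.0 SD 26.93, support [0, Inf)
  expect_lt(abs(mean(big$baseline_pwac) - 39.0), 3 * 26.93 / sqrt(n))
  expect_lt(abs(sd(big$baseline_pwac) - 26.93), 3 * 26.93 / sqrt(2 * n))
  # AUDIT: target mean 19.1 SD 6.66, support [8, 40] (eligible by construction)
  expect_lt(abs(mean(big$baseline_audit) - 19.1),
            3 * 6.66 / sqrt(n) + 0.05)  # integer rounding slack
  expect_lt(abs(sd(big$baseline_audit) - 6.66),
            3 * 6.66 / sqrt(2 * n) + 0.05)
  expect_gte(min(big$baseline_pwac), 0)
  expect_gte(min(big$baseline_audit), 8)
  expect_lte(max(big$baseline_audit), 40)
  expect_equal(nrow(filter_eligible(big)), n)  # eligibility by construction
})

test_that("per-phase response rates and the responder total behave binomially", {
  recs <- simulate_trial(sim_config(seed = 13L))  # default study conditions
  acct <- phase_accounting(recs)
  expect_equal(acct$n, c(672, 1914, 2586))
  # expected responders 672*0.266 + 1914*0.085 = 341.5, binomial SD ~ 16.7
  expected <- 672 * 0.266 + 1914 * 0.085
  bin_sd <- sqrt(672 * 0.266 * 0.734 + 1914 * 0.085 * 0.915)
  expect_lt(abs(acct$responders[3] - expected), 2.58 * bin_sd)  # 99% interval
  # responder flag consistent with follow-up presence
  expect_identical(recs$responded, !is.na(recs$followup_pwac))
})

test_that("null components stay null and injected effects propagate to change scores", {
  null_recs <- simulate_trial(sim_config(n_original = 32000L, n_extended = 0L,
                                         response_rate_original = 1,
                                         seed = 31L))
  aset <- change_scores(null_recs, "pwac")
  expect_lt(abs(mean(aset$values) - (-12.5)), 3 * sd(aset$values) / sqrt(32000))
  for (m in names(trial_modules())) {
    res <- main_effect(aset, m)
    expect_lt(abs(res$effect$mean_diff), 3 * res$effect$se)
  }

  eff_recs <- simulate_trial(sim_config(n_original = 32000L, n_extended = 0L,
                                        response_rate_original = 1,
                                        module_effects = c(nf = -5),
                                        interaction_effects = c("cbr:ap" = -4),
                                        seed = 32L))
  aset2 <- change_scores(eff_recs, "pwac")
  r_nf <- main_effect(aset2, "nf")
  expect_lt(abs(r_nf$effect$mean_diff - 5), 3 * r_nf$effect$se)
  # the pair contrast sees main-effect-free synergy: +4 on enhanced/enhanced
  r_int <- interaction_effect(aset2, c("cbr", "ap"))
  expect_lt(abs(r_int$effect$mean_diff - 4), 3 * r_int$effect$se)
})

test_that("the small fixture is a hand-checkable two-block cohort", {
  f <- fixture_small(17)
  expect_equal(nrow(f), 64L)
  cells <- interaction(f[paste0("mod_", names(trial_modules()))], drop = FALSE)
  expect_equal(as.integer(table(cells)), rep(2L, 32L))
  expect_true(all(f$responded))
  expect_identical(fixture_small(17), f)
  expect_false(identical(fixture_small(18)$mod_nf, f$mod_nf) &&
                 identical(fixture_small(18)$baseline_pwac, f$baseline_pwac))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(baseline_pwac_sd = 0), "baseline_pwac_sd")
  expect_error(sim_config(response_rate_original = 1.2),
               "response_rate_original")
  expect_error(sim_config(n_original = 8L, n_extended = 8L), "block")
  expect_error(sim_config(block_size = 30L), "multiple of 32")
  expect_error(sim_config(module_effects = c(zz = -5)), "module code")
  expect_error(sim_config(interaction_effects = c("nf-cbr" = 1)), "pair")
  expect_error(simulate_trial(list()), "sim_config")
})
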