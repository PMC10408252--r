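test_that("cutoff spec validation and fixed resolution", {
  expect_error(cutoff_spec(value = 0.01), "negative")
  expect_error(cutoff_spec(probs = 0), "probs")
  cut <- determine_cutoff(rnorm(50, 0, 0.01), cutoff_spec(value = -0.01))
  expect_equal(as.numeric(cut), -0.01)
  expect_identical(attr(cut, "method"), "fixed")
  expect_error(determine_cutoff(rnorm(10), cutoff_spec()), "at least 20")
})

test_that("gap method falls back to fixed when no cluster detaches", {
  # tight cluster around zero with a single straggler: no gap to measure
  res <- c(seq(0, 0.001, length.out = 19), -0.002)
  expect_warning(
    cut <- determine_cutoff(res, cutoff_spec("gap", value = -0.01)),
    "falling back")
  expect_equal(as.numeric(cut), -0.01)
  expect_identical(attr(cut, "method"), "fixed")
})

test_that("gap method separates a detached negative cluster (scan oracle)", {
  set.seed(42)
  res <- c(rnorm(300, 0, 0.002), rnorm(40, -0.05, 0.005))
  cut <- determine_cutoff(res, cutoff_spec("gap"))
  expect_identical(attr(cut, "method"), "gap")
  expect_gt(as.numeric(cut), -0.04)
  expect_lt(as.numeric(cut), -0.01)

  # independent oracle: exhaustive scan of all adjacent midpoints among
  # negative residuals below the lower quartile
  cand <- sort(res[res < 0 & res < quantile(res, 0.25)])
  gaps <- diff(cand)
  best <- which.max(gaps)
  expect_equal(as.numeric(cut), (cand[best] + cand[best + 1]) / 2)
  # the oracle cutoff separates the two planted clusters
  expect_equal(sum(res < as.numeric(cut)), 40)
})

test_that("classification is strict at the cutoff and ignores NA", {
  expect_true(classify_limbs(-0.02, -0.01))
  expect_false(classify_limbs(-0.01, -0.01))  # tie: not flagged
  expect_false(classify_limbs(NA, -0.01))
  expect_equal(classify_limbs(c(-0.5, 0.5, -0.010001), -0.01),
               c(TRUE, FALSE, TRUE))
})

test_that("regeneration index sums flagged present limbs only", {
  statuses <- c("intact", "intact", "bud", rep("intact", 7))
  masses <- c(0.05, 0.0391, 0.001, rep(0.2, 7))
  flags <- c(TRUE, TRUE, TRUE, rep(FALSE, 7))  # bud flag must be ignored
  expect_equal(regeneration_index(masses, flags, statuses), 0.0891)
  expect_equal(regeneration_index(masses, rep(FALSE, 10), statuses), 0)
  # monotone: growing a flagged limb grows the index
  masses2 <- masses
  masses2[1] <- masses[1] + 0.01
  expect_gt(regeneration_index(masses2, flags, statuses),
            regeneration_index(masses, flags, statuses))
})

test_that("imputation of absent limbs uses the allometric prediction", {
  fits <- lapply(1:10, function(l) manual_fit(2e-5, 3, limb_id = l))
  expect_equal(impute_missing_limb_mass(fits, rep("intact", 10), 20), 0)
  st <- rep("intact", 10)
  st[4] <- "missing"
  expect_equal(impute_missing_limb_mass(fits, st, 20), 0.16)
  st[7] <- "bud"  # buds count as absent for imputation
  expect_equal(impute_missing_limb_mass(fits, st, 20), 0.32)
  fits[[4]] <- manual_fit(2e-5, 3, limb_id = 4, converged = FALSE)
  expect_error(impute_missing_limb_mass(fits, st, 20), "limb 4")
})

test_that("imputation equals a manual per-limb sum on a handcrafted table", {
  fits <- lapply(1:10, function(l) manual_fit(1e-5 * l, 3, limb_id = l))
  set.seed(10)
  for (i in 1:5) {
    st <- sample(c("intact", "missing", "bud"), 10, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
    cw <- runif(1, 12, 32)
    manual <- 0
    for (l in 1:10)
      if (st[l] != "intact") manual <- manual + (1e-5 * l) * cw^3
    expect_equal(impute_missing_limb_mass(fits, st, cw), manual,
                 tolerance = 1e-12)
  }
})

test_that("corrected body mass adds imputed limbs to the organ-free body", {
  expect_equal(corrected_body_mass(2.0, 0), 2.0)
  expect_equal(corrected_body_mass(2.0, 0.16), 2.16)
  expect_error(corrected_body_mass(-1, 0.1), "units")
})

test_that("corrected body mass matches the generative law when uninjured", {
  cfg <- generator_config(n_crabs = 30, p_loss = 0, limb_noise_sd = 0,
                          organ_noise_sd = 0, molt_stage_range = c(1, 1),
                          seed = 66)
  pop <- generate_population(cfg)
  ta <- truth_assessment(pop)
  oa <- cfg$organ_allometry
  alpha <- oa$alpha[oa$organ == "body"]
  beta <- oa$beta[oa$organ == "body"]
  season <- seasonal_effect(pop$crabs$julian_day, cfg$season_amplitude,
                            cfg$season_peak_day)
  expect_equal(ta$corrected_body_mass_g,
               alpha * pop$crabs$carapace_width_mm^beta * season,
               tolerance = 1e-12)
})

test_that("per-crab bookkeeping conserves the ten limb slots", {
  pop <- generate_population(generator_config(n_crabs = 200, seed = 13))
  a <- assess_regeneration(pop$crabs)
  with(a$assessment, expect_equal(n_missing + n_buds + n_present,
                                  rep(10, 200)))
  # flags only on present limbs
  status <- as.matrix(pop$crabs[, sprintf("limb%02d_status", 1:10)])
  expect_true(all(status[a$flags] == "intact"))
  # regen mass zero iff nothing flagged
  expect_identical(a$assessment$regen_mass_total_g == 0,
                   a$assessment$n_regenerating == 0)
})

test_that("a more negative cutoff never flags more limbs", {
  pop <- generate_population(generator_config(n_crabs = 200, seed = 17))
  fits <- fit_all_limb_allometry(pop$crabs)
  a1 <- assess_regeneration(pop$crabs, fits, cutoff_spec(value = -0.005))
  a2 <- assess_regeneration(pop$crabs, fits, cutoff_spec(value = -0.02))
  expect_true(all(a2$flags <= a1$flags))
  expect_lte(sum(a2$flags), sum(a1$flags))
})

test_that("regeneration index is invariant to limb order and site labels", {
  set.seed(31)
  statuses <- sample(c("intact", "missing", "bud"), 10, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
  masses <- ifelse(statuses == "intact", runif(10, 0.05, 0.4), NA)
  flags <- statuses == "intact" & runif(10) < 0.5
  perm <- sample(10)
  expect_equal(regeneration_index(masses, flags, statuses),
               regeneration_index(masses[perm], flags[perm],
                                  statuses[perm]))
})

test_that("noiseless detection recovers the truth flags exactly", {
  cfg <- generator_config(n_crabs = 300, limb_noise_sd = 0,
                          molt_stage_range = c(1, 1),
                          regen_fraction_range = c(0.2, 0.9), seed = 55)
  pop <- generate_population(cfg)
  # zero noise: any mass deficit is regeneration, so the cutoff is half the
  # 0.01 mg balance resolution below zero; the iterative refit removes the
  # contamination of the fitted curve by the regenerating limbs themselves
  a <- assess_regeneration(pop$crabs, spec = cutoff_spec(value = -5e-6),
                           refit_excluding_flagged = TRUE)
  truth_partial <- matrix(pop$truth$limbs$true_status == "partial",
                          nrow(pop$crabs), 10, byrow = TRUE)
  expect_identical(unname(a$flags), unname(truth_partial))
})

test_that("injury summary: single uninjured crab and manual 3-crab tally", {
  one <- crab_row("U1")
  s1 <- summarize_injury(manual_assessment(one, matrix(FALSE, 1, 10)), one)
  expect_true(all(s1$per_limb[, -1] == 0))
  expect_equal(s1$totals$n_missing_total, 0)
  expect_equal(s1$totals$mean_regen_mass_mg, 0)

  crabs <- crab_table(
    crab_row("A", statuses = c("missing", "bud", rep("intact", 8))),
    crab_row("B", statuses = c("missing", rep("intact", 9))),
    crab_row("C")
  )
  flags <- matrix(FALSE, 3, 10)
  flags[3, 5] <- TRUE  # one regenerating limb on crab C
  s <- summarize_injury(manual_assessment(crabs, flags), crabs)
  expect_equal(s$per_limb$n_missing_no_bud, c(2, rep(0, 9)))
  expect_equal(s$per_limb$n_missing_with_bud, c(0, 1, rep(0, 8)))
  expect_equal(s$per_limb$n_regenerating, c(0, 0, 0, 0, 1, rep(0, 5)))
  expect_equal(s$totals$n_missing_total, 3)
  expect_equal(s$totals$n_existing_limbs, 27)
  expect_equal(s$totals$pct_missing_of_all, 100 * 3 / 30)
})

test_that("missing-limb percentage: 721 of 7360 slots is 9.8%", {
  # build a 736-crab table with exactly 721 absent limb slots
  n <- 736
  crabs <- do.call(rbind, lapply(seq_len(n), function(i) crab_row(
    sprintf("P%04d", i),
    statuses = if (i <= 721) c("missing", rep("intact", 9))
               else rep("intact", 10))))
  s <- summarize_injury(manual_assessment(crabs, matrix(FALSE, n, 10)),
                        crabs)
  expect_equal(s$totals$n_missing_total, 721)
  expect_equal(round(s$totals$pct_missing_of_all, 1), 9.8)
})
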