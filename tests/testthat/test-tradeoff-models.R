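make_world <- function(seed, n = 300, ...) {
  pop <- generate_population(generator_config(n_crabs = n, seed = seed, ...))
  ta <- truth_assessment(pop)
  list(pop = pop, ta = ta,
       bud = residualize_buds(ta$n_buds, ta$n_missing))
}

test_that("bud residualization: degenerate and independent cases", {
  expect_warning(r0 <- residualize_buds(rep(0, 50), rpois(50, 1)),
                 "all bud counts")
  expect_equal(r0$residuals, rep(0, 50))

  expect_error(residualize_buds(1:5, 1:4), "equal length")
  expect_error(residualize_buds(rep(1, 10), rep(1, 10)), "at least 30")
  expect_error(residualize_buds(c(-1, rep(1, 49)), rep(1, 50)),
               "non-negative")

  # independent counts: slope near zero, residuals track centered buds
  set.seed(5)
  nb <- rpois(400, 1.2)
  nm <- rpois(400, 0.8)
  r <- residualize_buds(nb, nm)
  expect_lt(abs(r$slope), 0.1)
  expect_lt(abs(cor(r$residuals, nm)), 0.05)
  expect_gt(cor(r$residuals, nb), 0.9)
})

test_that("bud residuals are decorrelated from missing counts", {
  w <- make_world(101, n = 736)
  expect_gt(cor(w$ta$n_buds, w$ta$n_missing), 0)  # collinear by design
  expect_lt(abs(cor(w$bud$residuals, w$ta$n_missing)), 0.05)
  expect_gt(w$bud$null_deviance, w$bud$residual_deviance)
})

test_that("a pure smooth response is absorbed: ~0 parametric effects", {
  cfg <- generator_config(n_crabs = 300, organ_noise_sd = 0,
                          season_amplitude = 0,
                          tradeoff_coeffs = within(default_tradeoff_coeffs(), {
                            beta_missing <- 0; beta_bud <- 0
                            beta_bud_sq <- 0; beta_regen <- 0
                          }), seed = 23)
  pop <- generate_population(cfg)
  ta <- truth_assessment(pop)
  bud <- residualize_buds(ta$n_buds, ta$n_missing)
  m <- fit_tradeoff_gam(ta$ovary_mass_g, ta, bud$residuals,
                        response_name = "ovary")
  expect_gt(m$deviance_explained, 0.999)
  est <- m$parametric[m$parametric$term != "(Intercept)", ]
  expect_true(all(abs(est$estimate) <= 2 * est$se_robust + 1e-8))
})

test_that("null world: zero coefficients recovered in >= 90% of 50 reps", {
  tc0 <- default_tradeoff_coeffs()
  tc0[, c("beta_missing", "beta_bud", "beta_bud_sq", "beta_regen")] <- 0
  hits <- matrix(NA, 50, 3,
                 dimnames = list(NULL, c("n_missing", "bud_resid",
                                         "regen_mass")))
  for (r in 1:50) {
    w <- make_world(4000 + r, n = 736, tradeoff_coeffs = tc0)
    m <- fit_tradeoff_gam(w$ta$ovary_mass_g, w$ta, w$bud$residuals,
                          response_name = "ovary")
    p <- m$parametric
    for (tm in colnames(hits))
      hits[r, tm] <- abs(p$estimate[p$term == tm]) <=
        2 * p$se_robust[p$term == tm]
  }
  # organ masses are conditionally independent of injury given CW and date
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("model selection: ties break linear; row mismatch errors", {
  w <- make_world(7, n = 300)
  lin <- fit_tradeoff_gam(w$ta$ovary_mass_g, w$ta, w$bud$residuals,
                          response_name = "ovary")
  lin2 <- lin
  lin2$label <- "quadratic(bud_resid)"
  sel <- select_model(lin, lin2)
  expect_identical(sel$label, "linear")
  expect_equal(sel$delta_aic, 0)

  w2 <- make_world(8, n = 310)
  lin3 <- fit_tradeoff_gam(w2$ta$ovary_mass_g, w2$ta, w2$bud$residuals,
                           response_name = "ovary")
  expect_error(select_model(lin, lin3), "different row sets")
})

test_that("quadratic form is selected when deviance demands it", {
  # nested-model property: quadratic never explains less
  w <- make_world(11, n = 400)
  lin <- fit_tradeoff_gam(w$ta$stomach_mass_g, w$ta, w$bud$residuals,
                          response_name = "stomach")
  quad <- fit_tradeoff_gam(w$ta$stomach_mass_g, w$ta, w$bud$residuals,
                           squared_terms = "bud_resid",
                           response_name = "stomach")
  expect_gte(quad$deviance_explained, lin$deviance_explained - 1e-10)
  sel <- select_model(lin, quad)
  expect_gte(sel$delta_aic, 0)
  expect_error(fit_tradeoff_gam(w$ta$stomach_mass_g, w$ta, w$bud$residuals,
                                squared_terms = "nope"), "unknown squared")
})

test_that("plotting residuals: perfect smooth and mean-zero property", {
  set.seed(9)
  cw <- runif(250, 12, 32)
  julian <- sample(61:316, 250, replace = TRUE)
  y_smooth <- 2e-4 * cw^3
  pr <- plotting_residuals(y_smooth, cw, julian)
  # a rank-10 penalized spline approximates rather than interpolates, so
  # "residuals ~ 0" means small relative to the response range
  expect_lt(max(abs(pr)) / diff(range(y_smooth)), 0.005)

  y_noisy <- y_smooth * exp(rnorm(250, 0, 0.2))
  pr2 <- plotting_residuals(y_noisy, cw, julian)
  expect_lt(abs(mean(pr2)), 1e-6)
})

test_that("covariate-adjusted ovary residuals decline across regen terciles", {
  pop <- generate_population(generator_config(seed = 303))
  a <- assess_regeneration(pop$crabs)$assessment
  pr <- plotting_residuals(a$ovary_mass_g, a$carapace_width_mm,
                           a$julian_day)
  terc <- cut(a$regen_mass_total_g,
              quantile(a$regen_mass_total_g, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = FALSE)
  means <- tapply(pr, terc, mean)
  expect_gt(means[[1]], means[[3]])  # direction check only
})

test_that("recovery report: exact linear world, symmetry, missing truth", {
  # zero organ noise, no seasonality: effects recovered almost exactly
  tc <- default_tradeoff_coeffs()
  cfg0 <- generator_config(n_crabs = 400, organ_noise_sd = 0,
                           season_amplitude = 0, seed = 61,
                           tradeoff_coeffs = tc)
  pop <- generate_population(cfg0)
  ta <- truth_assessment(pop)
  bud <- residualize_buds(ta$n_buds, ta$n_missing)
  m <- fit_tradeoff_gam(ta$ovary_mass_g, ta, bud$residuals,
                        response_name = "ovary")
  rr <- recovery_report(m, pop$truth, "ovary")
  regen <- rr[rr$term == "regen_mass", ]
  expect_lt(abs(regen$bias), 0.05 * abs(regen$truth))
  expect_true(regen$covered)

  # flipping the injected sign flips the estimate
  tc2 <- tc
  tc2$beta_regen[tc2$organ == "ovary"] <- 0.05311
  pop2 <- generate_population(generator_config(n_crabs = 400,
                                               organ_noise_sd = 0,
                                               season_amplitude = 0,
                                               seed = 61,
                                               tradeoff_coeffs = tc2))
  ta2 <- truth_assessment(pop2)
  bud2 <- residualize_buds(ta2$n_buds, ta2$n_missing)
  m2 <- fit_tradeoff_gam(ta2$ovary_mass_g, ta2, bud2$residuals,
                         response_name = "ovary")
  rr2 <- recovery_report(m2, pop2$truth, "ovary")
  expect_gt(rr2$estimate[rr2$term == "regen_mass"], 0)
  expect_lt(regen$estimate, 0)

  expect_error(recovery_report(m, list(tradeoff_coeffs = NULL), "ovary"),
               "lacks coefficients")
})

test_that("adding a constant shifts only the intercept", {
  w <- make_world(77, n = 300)
  m1 <- fit_tradeoff_gam(w$ta$ovary_mass_g, w$ta, w$bud$residuals,
                         response_name = "ovary")
  m2 <- fit_tradeoff_gam(w$ta$ovary_mass_g + 5, w$ta, w$bud$residuals,
                         response_name = "ovary")
  p1 <- m1$parametric
  p2 <- m2$parametric
  nonint <- p1$term != "(Intercept)"
  expect_equal(p2$estimate[nonint], p1$estimate[nonint], tolerance = 1e-6)
  expect_equal(p2$estimate[!nonint] - p1$estimate[!nonint], 5,
               tolerance = 1e-6)
})

test_that("estimates are invariant to crab order", {
  w <- make_world(78, n = 300)
  m1 <- fit_tradeoff_gam(w$ta$ovary_mass_g, w$ta, w$bud$residuals,
                         response_name = "ovary")
  set.seed(1)
  perm <- sample(nrow(w$ta))
  m2 <- fit_tradeoff_gam(w$ta$ovary_mass_g[perm], w$ta[perm, ],
                         w$bud$residuals[perm], response_name = "ovary")
  expect_equal(m2$parametric$estimate, m1$parametric$estimate,
               tolerance = 1e-8)
  expect_equal(m2$aic, m1$aic, tolerance = 1e-8)
})
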