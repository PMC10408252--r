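#' Cyclic seasonal organ-mass multiplier
#'
#' Organ condition in temperate crabs varies over the year (ovaries peak in
#' summer, storage organs track the foraging season). The generator applies
#' the multiplier `1 + amplitude * cos(2 * pi * (julian_day - peak_day) / 365)`
#' to the allometric organ mass. Period 365 days; the mean over a full year
#' is 1, so the multiplier redistributes rather than adds mass.
#'
#' @param julian_day Integer day-of-year, 1--366.
#' @param amplitude Relative amplitude, `0 <= amplitude < 1` (values >= 1
#'   are rejected: they would allow non-positive organ masses).
#' @param peak_day Julian day at which the multiplier peaks.
#' @return Numeric multiplier(s), same length as `julian_day`.
#' @examples
#' seasonal_effect(196, 0.3, 196)  # 1.3 at the peak
#' @export
seasonal_effect <- function(julian_day, amplitude, peak_day) {
  if (any(julian_day < 1) || any(julian_day > 366))
    stop("julian_day must lie in 1..366")
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1): >= 1 would allow a non-positive ",
         "organ-mass multiplier")
  1 + amplitude * cos(2 * pi * (julian_day - peak_day) / 365)
}

#' Generate a synthetic crab population with ground truth
#'
#' Draws a cross-sectional sample of crabs under the generative model stated
#' in [generator_config()]: uniform carapace width; per-limb power-law mass
#' `a_l * CW^b_l` times a shared molt-stage multiplier and lognormal noise;
#' per-limb injury states (missing / bud / partially regenerated) with
#' optional crab-level frailty; organ masses following power laws modulated
#' by season and lognormal noise, plus additive trade-off effects of the
#' number of missing limbs, the number of buds, and the summed mass of
#' partially regenerated limbs. Partially regenerated limbs appear in the
#' observed table as ordinary `intact` limbs at a fraction `f` of their
#' expected mass -- the downstream detection problem.
#'
#' @param config A [generator_config()].
#' @return A list of class `crab_population` with elements:
#'   \describe{
#'     \item{crabs}{Observed per-crab table (one row per crab): `crab_id`,
#'       `site`, `julian_day`, `carapace_width_mm`, `limb01_status` ...
#'       `limb10_status` (`intact`/`missing`/`bud`), `limb01_mass_g` ...
#'       `limb10_mass_g` (`NA` for missing limbs), and dry masses
#'       `ovary_mass_g`, `hepatopancreas_mass_g`, `stomach_mass_g`,
#'       `body_rest_mass_g`.}
#'     \item{truth}{Ground truth: `$limbs` has one row per crab-limb with
#'       the true status (`intact`/`missing`/`bud`/`partial`), the true
#'       regeneration fraction `f` (`NA` unless partial) and the expected
#'       uninjured limb mass; `$tradeoff_coeffs` echoes the injected
#'       coefficients; `$config` echoes the full configuration.}
#'     \item{n_floor_events}{Count of organ masses floored at zero.}
#'   }
#' @export
generate_population <- function(config) {
  validate_generator_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_crabs
    crab_id <- sprintf("C%05d", seq_len(n))

    sched <- cfg$sampling_schedule
    pick <- sample.int(nrow(sched), n, replace = TRUE,
                       prob = sched$weight / sum(sched$weight))
    site <- sched$site[pick]
    julian_day <- as.integer(sched$julian_day[pick])

    cw <- runif(n, cfg$cw_range[1], cfg$cw_range[2])
    molt <- runif(n, cfg$molt_stage_range[1], cfg$molt_stage_range[2])

    p_crab <- if (cfg$loss_heterogeneity_sd > 0) {
      s <- cfg$loss_heterogeneity_sd
      pmin(cfg$p_loss * exp(rnorm(n, -s^2 / 2, s)), 1)
    } else rep(cfg$p_loss, n)

    status_obs <- matrix("intact", n, 10)
    status_true <- matrix("intact", n, 10)
    mass_obs <- matrix(NA_real_, n, 10)
    frac_true <- matrix(NA_real_, n, 10)
    expected <- matrix(NA_real_, n, 10)

    for (l in 1:10) {
      exp_l <- cfg$limb_a[l] * cw^cfg$limb_b[l]
      expected[, l] <- exp_l
      lost <- runif(n) < p_crab
      u <- runif(n)  # drawn for every crab to keep the stream rectangular
      state <- ifelse(!lost, "intact",
               ifelse(u < cfg$p_bud_given_loss, "bud",
               ifelse(u < cfg$p_bud_given_loss + cfg$p_partial_given_loss,
                      "partial", "missing")))
      status_true[, l] <- state

      noise <- if (cfg$limb_noise_sd > 0)
        exp(rnorm(n, 0, cfg$limb_noise_sd)) else rep(1, n)
      f <- runif(n, cfg$regen_fraction_range[1], cfg$regen_fraction_range[2])
      budf <- runif(n, cfg$bud_mass_fraction_range[1],
                    cfg$bud_mass_fraction_range[2])

      i <- state == "intact"
      mass_obs[i, l] <- exp_l[i] * molt[i] * noise[i]
      i <- state == "partial"  # partial regrowth: fraction f, no extra noise
      mass_obs[i, l] <- f[i] * exp_l[i] * molt[i]
      frac_true[i, l] <- f[i]
      status_obs[i, l] <- "intact"
      i <- state == "bud"
      mass_obs[i, l] <- budf[i] * exp_l[i]
      status_obs[i, l] <- "bud"
      status_obs[state == "missing", l] <- "missing"
    }

    n_missing <- rowSums(status_true == "missing")
    n_buds <- rowSums(status_true == "bud")
    partial_mass <- rowSums(ifelse(status_true == "partial", mass_obs, 0))

    organs <- matrix(NA_real_, n, length(ORGANS),
                     dimnames = list(NULL, ORGANS))
    season <- seasonal_effect(julian_day, cfg$season_amplitude,
                              cfg$season_peak_day)
    n_floor <- 0L
    for (org in ORGANS) {
      oa <- cfg$organ_allometry[cfg$organ_allometry$organ == org, ]
      tc <- cfg$tradeoff_coeffs[cfg$tradeoff_coeffs$organ == org, ]
      noise <- if (cfg$organ_noise_sd > 0)
        exp(rnorm(n, 0, cfg$organ_noise_sd)) else rep(1, n)
      y <- oa$alpha * cw^oa$beta * season * noise +
        tc$beta_missing * n_missing + tc$beta_bud * n_buds +
        tc$beta_bud_sq * n_buds^2 + tc$beta_regen * partial_mass
      floored <- y < 0
      if (any(floored)) {
        n_floor <- n_floor + sum(floored)
        y[floored] <- 0
      }
      organs[, org] <- y
    }
    if (n_floor > 0)
      message("generate_population: ", n_floor,
              " organ mass(es) floored at 0")

    crabs <- data.frame(crab_id = crab_id, site = site,
                        julian_day = julian_day, carapace_width_mm = cw,
                        stringsAsFactors = FALSE)
    for (l in 1:10) crabs[[limb_status_col(l)]] <- status_obs[, l]
    for (l in 1:10) crabs[[limb_mass_col(l)]] <- mass_obs[, l]
    crabs$ovary_mass_g <- organs[, "ovary"]
    crabs$hepatopancreas_mass_g <- organs[, "hepatopancreas"]
    crabs$stomach_mass_g <- organs[, "stomach"]
    crabs$body_rest_mass_g <- organs[, "body"]

    truth_limbs <- data.frame(
      crab_id = rep(crab_id, each = 10),
      limb_id = rep(1:10, times = n),
      true_status = as.vector(t(status_true)),
      regen_fraction = as.vector(t(frac_true)),
      expected_mass_g = as.vector(t(expected)),
      stringsAsFactors = FALSE
    )

    out <- list(
      crabs = crabs,
      truth = list(limbs = truth_limbs,
                   tradeoff_coeffs = cfg$tradeoff_coeffs,
                   config = cfg),
      n_floor_events = n_floor
    )
    class(out) <- "crab_population"
    out
  })
}

#' @export
print.crab_population <- function(x, ...) {
  cat("Synthetic crab population:", nrow(x$crabs), "crabs\n")
  st <- table(factor(x$truth$limbs$true_status,
                     levels = c("intact", "missing", "bud", "partial")))
  cat("  true limb states:",
      paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a crab population as CSV
#'
#' `write_population()` writes the observed table and (optionally) the truth
#' sidecar; `read_crab_table()` reads an observed table back. Plain CSV, one
#' row per crab, full numeric precision.
#'
#' @param population A `crab_population` (or a bare crab data frame).
#' @param path Output CSV path for the observed table.
#' @param truth_path Optional path for the truth sidecar CSV.
#' @return The input, invisibly (`read_crab_table()` returns a data frame).
#' @export
write_population <- function(population, path, truth_path = NULL) {
  crabs <- if (inherits(population, "crab_population"))
    population$crabs else population
  write.csv(format_numeric(crabs), path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path) && inherits(population, "crab_population"))
    write.csv(format_numeric(population$truth$limbs), truth_path,
              row.names = FALSE, quote = FALSE)
  invisible(population)
}

#' @rdname write_population
#' @export
read_crab_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Full-precision, locale-stable numeric formatting for CSV output.
format_numeric <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         format(df[[nm]], digits = 17, trim = TRUE,
                                scientific = FALSE))
  }
  df
}

#' Per-crab predictor table from the ground truth
#'
#' Builds the same per-crab table as [assess_regeneration()]`$assessment`
#' but from the generator's truth rather than from detection: true counts
#' of missing and budding limbs, the true summed mass of partially
#' regenerated limbs, and an expected-missing-mass imputation taken from
#' the generative allometry itself. Used by parameter-recovery simulations,
#' where the injected trade-off coefficients are defined with respect to
#' these true predictors; the detection-based index adds measurement error
#' (false flags carry full-mass limbs) that attenuates fitted coefficients.
#'
#' @param population A `crab_population` from [generate_population()].
#' @return Data frame with the assessment-table columns.
#' @export
truth_assessment <- function(population) {
  stopifnot(inherits(population, "crab_population"))
  crabs <- population$crabs
  tl <- population$truth$limbs
  n <- nrow(crabs)
  st <- matrix(tl$true_status, nrow = n, ncol = 10, byrow = TRUE)
  mass <- as.matrix(crabs[, limb_mass_col(1:10)])
  expm <- matrix(tl$expected_mass_g, nrow = n, ncol = 10, byrow = TRUE)
  absent <- st == "missing" | st == "bud"
  exp_missing <- rowSums(ifelse(absent, expm, 0))
  data.frame(
    crab_id = crabs$crab_id, site = crabs$site,
    julian_day = crabs$julian_day,
    carapace_width_mm = crabs$carapace_width_mm,
    n_missing = rowSums(st == "missing"),
    n_buds = rowSums(st == "bud"),
    n_present = rowSums(st == "intact" | st == "partial"),
    n_regenerating = rowSums(st == "partial"),
    regen_mass_total_g = rowSums(ifelse(st == "partial", mass, 0)),
    expected_missing_mass_g = exp_missing,
    corrected_body_mass_g = crabs$body_rest_mass_g + exp_missing,
    ovary_mass_g = crabs$ovary_mass_g,
    hepatopancreas_mass_g = crabs$hepatopancreas_mass_g,
    stomach_mass_g = crabs$stomach_mass_g,
    body_rest_mass_g = crabs$body_rest_mass_g,
    stringsAsFactors = FALSE
  )
}
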