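#' Default field sampling schedule
#'
#' Site-by-day sampling schedule used by [generate_population()] to draw each
#' synthetic crab's collection site and Julian sampling day. The default
#' mirrors a five-site, March--November survey of the western Atlantic range
#' of *Hemigrapsus sanguineus* (sampling days 61--316), with draw weights
#' proportional to the per-visit sample sizes of that survey.
#'
#' @return A data frame with columns `site`, `julian_day` and `weight`.
#' @export
default_sampling_schedule <- function() {
  sched <- list(
    ME = list(days = c(75, 133, 192, 252, 314), n = c(20, 30, 41, 34, 32)),
    NH = list(days = c(61, 133, 194, 251, 313), n = c(24, 32, 33, 36, 32)),
    CT = list(days = c(63, 75, 93, 136, 165, 181, 194, 226, 256, 285, 316),
              n = c(21, 27, 33, 30, 30, 30, 3, 30, 28, 26, 30)),
    NJ = list(days = c(66, 131, 193, 258), n = c(18, 35, 35, 33)),
    NC = list(days = c(75, 136, 197, 259), n = c(27, 30, 5, 14))
  )
  out <- do.call(rbind, lapply(names(sched), function(s) {
    data.frame(site = s, julian_day = sched[[s]]$days, weight = sched[[s]]$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default per-organ power-law coefficients
#'
#' Dry organ mass scales as `alpha * CW^beta` (grams, CW in mm). Defaults are
#' chosen so a 22 mm female carries roughly 0.06 g of stomach contents,
#' 0.2 g of ovary, 0.26 g of hepatopancreas and 2 g of remaining body --
#' realistic magnitudes for an adult shore crab.
#'
#' @return Data frame with columns `organ`, `alpha`, `beta`.
#' @export
default_organ_allometry <- function() {
  data.frame(
    organ = ORGANS,
    alpha = c(6e-6, 1.2e-5, 2.5e-5, 2e-4),
    beta  = c(2.9, 3.15, 3.0, 3.0),
    stringsAsFactors = FALSE
  )
}

#' Default injected trade-off coefficients
#'
#' Organ-mass change (g) per additional missing limb (`beta_missing`), per
#' additional limb bud (`beta_bud`), per squared bud count (`beta_bud_sq`),
#' and per gram of partially regenerated limb mass (`beta_regen`). Defaults
#' are field-realistic point estimates for this system: ovary mass falls by
#' about 53 mg and hepatopancreas mass by about 74 mg per gram of regenerated
#' tissue, hepatopancreas mass by about 4.9 mg per currently missing limb,
#' and somatic (rest-of-body) mass by 1.24 g per gram regenerated while
#' rising ~37 mg per limb bud; effects never reported as distinguishable
#' from zero default to zero.
#'
#' @return Data frame with columns `organ`, `beta_missing`, `beta_bud`,
#'   `beta_bud_sq`, `beta_regen`.
#' @export
default_tradeoff_coeffs <- function() {
  data.frame(
    organ        = ORGANS,
    beta_missing = c(0, 0, -0.00488, 0),
    beta_bud     = c(0, 0, 0, 0.03662),
    beta_bud_sq  = c(0, 0, 0, 0),
    beta_regen   = c(0, -0.05311, -0.07376, -1.24),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic crab-population generator
#'
#' Bundles every parameter of the generative model behind
#' [generate_population()]. The defaults describe a single stated world:
#' a 736-crab cross-sectional sample with ~24% of limb slots ever injured
#' (of which 29% currently bear a bud, 59% are partially regenerated and the
#' rest are bare losses), cubic-law limb and organ allometry with ~10%
#' multiplicative limb noise, a shared within-crab molt-stage multiplier,
#' cyclic seasonal organ-mass variation peaking in mid-July, and additive
#' trade-off effects of injury state on organ masses.
#'
#' @param n_crabs Number of crabs to simulate.
#' @param cw_range Carapace-width range (mm); CW is drawn uniformly.
#' @param limb_a,limb_b Length-10 vectors of per-limb power-law coefficients
#'   (`mass = a * CW^b`, grams and mm). Limbs are numbered 1 = right claw,
#'   clockwise to 10 = left claw; claws are heavier than walking legs.
#' @param limb_noise_sd SD (log scale) of multiplicative lognormal limb-mass
#'   noise.
#' @param molt_stage_range Bounds of the uniform within-crab molt-stage mass
#'   multiplier, shared by all of a crab's limbs.
#' @param p_loss Per-limb probability that the limb was lost at some point
#'   (currently missing, budding, or partially regenerated).
#' @param p_bud_given_loss,p_partial_given_loss Conditional probabilities of
#'   the bud and partial-regeneration states given loss (their sum must be
#'   at most 1; the remainder is a bare missing limb).
#' @param regen_fraction_range Range of the fraction `f` of expected limb
#'   mass attained by a partially regenerated limb; `f_min < f_max < 1`.
#' @param bud_mass_fraction_range Recorded bud mass as a fraction of expected
#'   limb mass (buds are tiny nascent limbs still in their cuticular sac).
#' @param organ_allometry Data frame as [default_organ_allometry()].
#' @param season_amplitude,season_peak_day Amplitude (must be < 1) and peak
#'   Julian day of the cyclic seasonal organ-mass multiplier
#'   `1 + A * cos(2 * pi * (day - peak) / 365)`.
#' @param tradeoff_coeffs Data frame as [default_tradeoff_coeffs()].
#' @param organ_noise_sd SD (log scale) of multiplicative lognormal organ
#'   noise.
#' @param loss_heterogeneity_sd SD (log scale) of a mean-one lognormal
#'   crab-level frailty multiplying `p_loss`. Positive values make injury
#'   states cluster within crabs, reproducing the positive missing~bud
#'   collinearity seen in field samples; 0 gives independent per-limb loss.
#' @param sampling_schedule Data frame as [default_sampling_schedule()].
#' @param seed Mandatory integer seed; identical config (seed included)
#'   yields byte-identical output.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_crabs = 736,
                             cw_range = c(12, 32),
                             limb_a = c(2.5e-5, 1.3e-5, 1.5e-5, 1.6e-5,
                                        1.5e-5, 1.4e-5, 1.5e-5, 1.6e-5,
                                        1.4e-5, 2.5e-5),
                             limb_b = rep(3, 10),
                             limb_noise_sd = 0.1,
                             molt_stage_range = c(0.9, 1.1),
                             p_loss = 0.24,
                             p_bud_given_loss = 0.29,
                             p_partial_given_loss = 0.59,
                             regen_fraction_range = c(0.2, 0.7),
                             bud_mass_fraction_range = c(0.005, 0.05),
                             organ_allometry = default_organ_allometry(),
                             season_amplitude = 0.25,
                             season_peak_day = 196,
                             tradeoff_coeffs = default_tradeoff_coeffs(),
                             organ_noise_sd = 0.15,
                             loss_heterogeneity_sd = 0.6,
                             sampling_schedule = default_sampling_schedule(),
                             seed) {
  if (missing(seed)) stop("generator_config: `seed` is mandatory")
  cfg <- list(
    n_crabs = as.integer(n_crabs), cw_range = as.numeric(cw_range),
    limb_a = as.numeric(limb_a), limb_b = as.numeric(limb_b),
    limb_noise_sd = as.numeric(limb_noise_sd),
    molt_stage_range = as.numeric(molt_stage_range),
    p_loss = as.numeric(p_loss),
    p_bud_given_loss = as.numeric(p_bud_given_loss),
    p_partial_given_loss = as.numeric(p_partial_given_loss),
    regen_fraction_range = as.numeric(regen_fraction_range),
    bud_mass_fraction_range = as.numeric(bud_mass_fraction_range),
    organ_allometry = as.data.frame(organ_allometry),
    season_amplitude = as.numeric(season_amplitude),
    season_peak_day = as.numeric(season_peak_day),
    tradeoff_coeffs = as.data.frame(tradeoff_coeffs),
    organ_noise_sd = as.numeric(organ_noise_sd),
    loss_heterogeneity_sd = as.numeric(loss_heterogeneity_sd),
    sampling_schedule = as.data.frame(sampling_schedule),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  fail <- function(...) stop("invalid generator_config: ", ..., call. = FALSE)
  if (length(cfg$n_crabs) != 1 || is.na(cfg$n_crabs) || cfg$n_crabs < 1)
    fail("n_crabs must be a positive integer")
  if (length(cfg$cw_range) != 2 || cfg$cw_range[1] <= 0 ||
      cfg$cw_range[1] > cfg$cw_range[2])
    fail("cw_range must be 0 < min <= max")
  if (length(cfg$limb_a) != 10 || any(cfg$limb_a <= 0))
    fail("limb_a must be 10 positive values")
  if (length(cfg$limb_b) != 10) fail("limb_b must have length 10")
  for (p in c("p_loss", "p_bud_given_loss", "p_partial_given_loss")) {
    v <- cfg[[p]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      fail(p, " must lie in [0, 1]")
  }
  if (cfg$p_bud_given_loss + cfg$p_partial_given_loss > 1)
    fail("p_bud_given_loss + p_partial_given_loss must be <= 1")
  fr <- cfg$regen_fraction_range
  if (length(fr) != 2 || fr[1] < 0 || fr[1] >= fr[2] || fr[2] >= 1)
    fail("regen_fraction_range must satisfy 0 <= f_min < f_max < 1")
  br <- cfg$bud_mass_fraction_range
  if (length(br) != 2 || br[1] < 0 || br[1] > br[2])
    fail("bud_mass_fraction_range must be ordered and non-negative")
  if (cfg$limb_noise_sd < 0 || cfg$organ_noise_sd < 0 ||
      cfg$loss_heterogeneity_sd < 0)
    fail("noise SDs must be non-negative")
  mr <- cfg$molt_stage_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[1] > mr[2])
    fail("molt_stage_range must be 0 < lo <= hi")
  if (cfg$season_amplitude < 0 || cfg$season_amplitude >= 1)
    fail("season_amplitude must lie in [0, 1)")
  oa <- cfg$organ_allometry
  if (!all(c("organ", "alpha", "beta") %in% names(oa)) ||
      !setequal(oa$organ, ORGANS))
    fail("organ_allometry must cover organs: ", paste(ORGANS, collapse = ", "))
  if (any(oa$alpha <= 0)) fail("organ allometry alpha must be positive")
  tc <- cfg$tradeoff_coeffs
  need <- c("organ", "beta_missing", "beta_bud", "beta_bud_sq", "beta_regen")
  if (!all(need %in% names(tc)) || !setequal(tc$organ, ORGANS))
    fail("tradeoff_coeffs must have columns ",
         paste(need, collapse = ", "), " covering all organs")
  ss <- cfg$sampling_schedule
  if (!all(c("site", "julian_day", "weight") %in% names(ss)) ||
      any(ss$julian_day < 1) || any(ss$julian_day > 366) ||
      any(ss$weight <= 0))
    fail("sampling_schedule needs site, julian_day in 1..366, positive weight")
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed must be an integer")
  invisible(cfg)
}

#' Write / read a generator configuration
#'
#' Serialized as structured JSON text so a run's configuration travels with
#' its outputs. Round-trips exactly up to double-precision printing
#' (`digits = NA` keeps full precision).
#'
#' @param config A [generator_config()] object.
#' @param path File path.
#' @return `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$organ_allometry <- as.data.frame(raw$organ_allometry)
  raw$tradeoff_coeffs <- as.data.frame(raw$tradeoff_coeffs)
  raw$sampling_schedule <- as.data.frame(raw$sampling_schedule)
  do.call(generator_config, raw)
}
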