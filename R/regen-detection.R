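#' Specify how the regeneration cutoff is resolved
#'
#' A limb is classified as historically regenerating when its allometric
#' residual falls strictly below a negative cutoff. Three ways to resolve
#' the cutoff from a limb's residual distribution:
#' \describe{
#'   \item{`fixed`}{use `value` as-is (default -0.01 g, the residual mass at
#'     which negative residuals typically break away from the main cluster
#'     in field samples of this size range);}
#'   \item{`gap`}{automated analogue of the visual break: the midpoint of
#'     the largest inter-point gap among sorted negative residuals lying
#'     below the lower quartile of all residuals;}
#'   \item{`quantile`}{the `probs` lower sample quantile of the residuals.}
#' }
#' `gap` and `quantile` fall back to `fixed` (with a warning) when they
#' cannot resolve a negative cutoff.
#'
#' @param method One of `"fixed"`, `"gap"`, `"quantile"`.
#' @param value Cutoff in grams for the `fixed` method (and the fallback);
#'   must be negative.
#' @param probs Lower-tail probability for the `quantile` method.
#' @return A `cutoff_spec` list.
#' @export
cutoff_spec <- function(method = c("fixed", "gap", "quantile"),
                        value = -0.01, probs = 0.05) {
  method <- match.arg(method)
  if (value >= 0) stop("cutoff value must be negative (a deficit in mass)")
  if (probs <= 0 || probs >= 1) stop("probs must lie in (0, 1)")
  structure(list(method = method, value = value, probs = probs),
            class = "cutoff_spec")
}

#' Resolve the regeneration cutoff for one limb's residuals
#'
#' @param residuals Mass-scale residuals (g) from [fit_limb_allometry()].
#' @param spec A [cutoff_spec()].
#' @return The resolved cutoff (g, negative), with attribute `method`
#'   recording the method actually used (after any fallback).
#' @export
determine_cutoff <- function(residuals, spec = cutoff_spec()) {
  stopifnot(inherits(spec, "cutoff_spec"))
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 20)
    stop("determine_cutoff: need at least 20 residuals, got ",
         length(residuals))
  fallback <- function(why) {
    warning("determine_cutoff: ", why, "; falling back to fixed cutoff ",
            spec$value, " g", call. = FALSE)
    structure(spec$value, method = "fixed")
  }
  out <- switch(spec$method,
    fixed = structure(spec$value, method = "fixed"),
    quantile = {
      q <- unname(quantile(residuals, spec$probs, type = 7))
      if (q >= 0) fallback("lower quantile is non-negative")
      else structure(q, method = "quantile")
    },
    gap = {
      lower_q <- unname(quantile(residuals, 0.25, type = 7))
      cand <- sort(residuals[residuals < 0 & residuals < lower_q])
      if (length(cand) < 2) fallback("no detached negative cluster")
      else {
        gaps <- diff(cand)
        i <- which.max(gaps)
        if (gaps[i] <= 0) fallback("negative residuals are degenerate")
        else structure((cand[i] + cand[i + 1]) / 2, method = "gap")
      }
    }
  )
  out
}

#' Classify limbs as historically regenerating
#'
#' A limb is flagged iff its residual is strictly below the cutoff; a
#' residual exactly equal to the cutoff is not flagged.
#'
#' @param residuals Residuals (g); `NA` (absent limbs) are never flagged.
#' @param cutoff Resolved negative cutoff (g).
#' @return Logical vector of flags, same length/names as `residuals`.
#' @export
classify_limbs <- function(residuals, cutoff) {
  !is.na(residuals) & residuals < as.numeric(cutoff)
}

#' Per-crab regenerated-mass index
#'
#' Sum of the dry masses of a crab's limbs flagged as regenerating; bud
#' masses are never included (buds are not weighed as limbs). A continuous
#' proxy for the energy already allocated to regrowing lost limbs.
#'
#' @param limb_masses Length-10 vector of observed limb masses (g; `NA`
#'   where absent).
#' @param flags Length-10 logical vector from [classify_limbs()].
#' @param statuses Length-10 status vector (`intact`/`missing`/`bud`).
#' @return Total regenerated dry mass (g).
#' @export
regeneration_index <- function(limb_masses, flags, statuses) {
  keep <- flags & statuses == "intact" & !is.na(limb_masses)
  sum(limb_masses[keep])
}

#' Expected mass of a crab's absent limbs
#'
#' Sums `predict_limb_mass()` over the crab's absent limb positions (status
#' `missing` or `bud`): a bud is not a functioning limb and its recorded
#' mass, if any, is a token. Requires a converged fit at each absent
#' position.
#'
#' @param fits List of ten `allometric_fit` objects.
#' @param statuses Length-10 status vector.
#' @param cw Carapace width (mm).
#' @return Expected total absent-limb dry mass (g).
#' @export
impute_missing_limb_mass <- function(fits, statuses, cw) {
  absent <- which(statuses %in% c("missing", "bud"))
  if (length(absent) == 0) return(0)
  total <- 0
  for (l in absent) {
    f <- fits[[l]]
    if (!isTRUE(f$converged))
      stop("impute_missing_limb_mass: fit for limb ", l, " not converged")
    total <- total + predict_limb_mass(f, cw)
  }
  total
}

#' Corrected body mass
#'
#' Somatic-growth proxy: the rest-of-body dry mass (organs were dissected
#' out before drying, so ovary and hepatopancreas are already excluded)
#' plus the expected mass of the limbs that are absent. For an uninjured
#' crab this equals `body_rest_mass` exactly.
#'
#' @param body_rest_mass Rest-of-body dry mass (g).
#' @param expected_missing_mass Output of [impute_missing_limb_mass()].
#' @return Corrected body mass (g).
#' @export
corrected_body_mass <- function(body_rest_mass, expected_missing_mass) {
  out <- body_rest_mass + expected_missing_mass
  if (any(out < 0, na.rm = TRUE))
    stop("corrected_body_mass is negative: check input units")
  out
}

#' Assess injury and regeneration for every crab
#'
#' Runs the full detection stage: resolves a cutoff per limb position from
#' that limb's residual distribution, classifies each present limb, and
#' builds the per-crab assessment used by the trade-off models.
#'
#' @param crabs Crab table.
#' @param fits List of ten `allometric_fit` objects (default: fitted here).
#' @param spec A [cutoff_spec()].
#' @param refit_excluding_flagged If `TRUE`, iteratively refit each limb's
#'   allometry excluding currently flagged limbs until the flag set is
#'   stable (at most `max_refit` rounds). Off by default: the reference
#'   procedure is a single pass with regenerating limbs included in the
#'   fit, which biases the fitted curve slightly downwards; the iterative
#'   mode removes that contamination.
#' @param max_refit Maximum refit rounds.
#' @return A `regen_assessment` list:
#'   \describe{
#'     \item{assessment}{Per-crab data frame: `crab_id`, `site`,
#'       `julian_day`, `carapace_width_mm`, `n_missing` (absent, no bud),
#'       `n_buds`, `n_present`, `n_regenerating`, `regen_mass_total_g`,
#'       `expected_missing_mass_g`, `corrected_body_mass_g` plus the organ
#'       masses carried through.}
#'     \item{flags}{n x 10 logical matrix of regenerating flags (present
#'       limbs only).}
#'     \item{cutoffs}{Per-limb resolved cutoffs with methods.}
#'     \item{fits}{The allometric fits used.}
#'   }
#' @export
assess_regeneration <- function(crabs, fits = fit_all_limb_allometry(crabs),
                                spec = cutoff_spec(),
                                refit_excluding_flagged = FALSE,
                                max_refit = 5) {
  n <- nrow(crabs)
  status <- as.matrix(crabs[, limb_status_col(1:10)])
  mass <- as.matrix(crabs[, limb_mass_col(1:10)])

  classify_round <- function(fits) {
    cutoffs <- numeric(10)
    methods <- character(10)
    flags <- matrix(FALSE, n, 10)
    resid_mat <- matrix(NA_real_, n, 10)
    for (l in 1:10) {
      f <- fits[[l]]
      if (!isTRUE(f$converged))
        stop("assess_regeneration: unconverged allometric fit for limb ", l,
             "; refusing to classify")
      cut_l <- determine_cutoff(f$residuals, spec)
      cutoffs[l] <- as.numeric(cut_l)
      methods[l] <- attr(cut_l, "method")
      r <- rep(NA_real_, n)
      idx <- match(names(f$residuals), crabs$crab_id)
      r[idx] <- f$residuals
      r[status[, l] != "intact"] <- NA  # only present limbs carry residuals
      resid_mat[, l] <- r
      flags[, l] <- classify_limbs(r, cutoffs[l])
    }
    list(cutoffs = cutoffs, methods = methods, flags = flags,
         resid_mat = resid_mat)
  }

  round <- classify_round(fits)
  if (refit_excluding_flagged) {
    for (it in seq_len(max_refit)) {
      fits2 <- lapply(1:10, function(l)
        fit_limb_allometry(crabs, l,
                           exclude_crab_ids =
                             crabs$crab_id[round$flags[, l]]))
      round2 <- classify_round(fits2)
      stable <- identical(round2$flags, round$flags)
      fits <- fits2
      round <- round2
      if (stable) break
    }
  }
  cutoffs <- round$cutoffs
  methods <- round$methods
  flags <- round$flags
  resid_mat <- round$resid_mat

  n_missing <- rowSums(status == "missing")
  n_buds <- rowSums(status == "bud")
  n_present <- rowSums(status == "intact")
  n_regen <- rowSums(flags)
  regen_mass <- vapply(seq_len(n), function(i)
    regeneration_index(mass[i, ], flags[i, ], status[i, ]), numeric(1))
  exp_missing <- vapply(seq_len(n), function(i)
    impute_missing_limb_mass(fits, status[i, ], crabs$carapace_width_mm[i]),
    numeric(1))
  corr_body <- corrected_body_mass(crabs$body_rest_mass_g, exp_missing)

  assessment <- data.frame(
    crab_id = crabs$crab_id, site = crabs$site,
    julian_day = crabs$julian_day,
    carapace_width_mm = crabs$carapace_width_mm,
    n_missing = n_missing, n_buds = n_buds, n_present = n_present,
    n_regenerating = n_regen,
    regen_mass_total_g = regen_mass,
    expected_missing_mass_g = exp_missing,
    corrected_body_mass_g = corr_body,
    ovary_mass_g = crabs$ovary_mass_g,
    hepatopancreas_mass_g = crabs$hepatopancreas_mass_g,
    stomach_mass_g = crabs$stomach_mass_g,
    body_rest_mass_g = crabs$body_rest_mass_g,
    stringsAsFactors = FALSE
  )
  out <- list(assessment = assessment, flags = flags,
              residuals = resid_mat,
              cutoffs = data.frame(limb_id = 1:10, cutoff_g = cutoffs,
                                   method = methods),
              fits = fits)
  class(out) <- "regen_assessment"
  out
}

#' @export
print.regen_assessment <- function(x, ...) {
  a <- x$assessment
  cat("Regeneration assessment:", nrow(a), "crabs\n")
  cat(sprintf("  missing (no bud): %d limbs; buds: %d; regenerating: %d\n",
              sum(a$n_missing), sum(a$n_buds), sum(a$n_regenerating)))
  cat(sprintf("  regen mass per crab: %.1f +/- %.1f mg\n",
              1000 * mean(a$regen_mass_total_g),
              1000 * sd(a$regen_mass_total_g)))
  invisible(x)
}

#' Injury summary by limb position and population totals
#'
#' Tabulates, for each limb position, the limbs currently missing without a
#' bud, missing with a bud, and historically regenerating, plus population
#' totals under both counting conventions (missing including vs excluding
#' bud-bearing limbs), percentages of all limb slots and of existing limbs,
#' and per-crab means.
#'
#' @param x A `regen_assessment`.
#' @param crabs The crab table the assessment came from.
#' @return List with `per_limb` (data frame) and `totals` (named list).
#' @export
summarize_injury <- function(x, crabs) {
  stopifnot(inherits(x, "regen_assessment"))
  status <- as.matrix(crabs[, limb_status_col(1:10)])
  per_limb <- data.frame(
    limb_id = 1:10,
    n_missing_no_bud = colSums(status == "missing"),
    n_missing_with_bud = colSums(status == "bud"),
    n_regenerating = colSums(x$flags)
  )
  n_slots <- 10 * nrow(crabs)
  n_existing <- sum(status == "intact")
  tot_missing <- sum(per_limb$n_missing_no_bud) +
    sum(per_limb$n_missing_with_bud)
  tot_regen <- sum(per_limb$n_regenerating)
  a <- x$assessment
  totals <- list(
    n_crabs = nrow(crabs),
    n_limb_slots = n_slots,
    n_existing_limbs = n_existing,
    n_missing_total = tot_missing,
    n_missing_no_bud = sum(per_limb$n_missing_no_bud),
    n_missing_with_bud = sum(per_limb$n_missing_with_bud),
    pct_missing_of_all = 100 * tot_missing / n_slots,
    n_regenerating = tot_regen,
    pct_regenerating_of_existing = 100 * tot_regen / n_existing,
    pct_missing_or_regen_of_all = 100 * (tot_missing + tot_regen) / n_slots,
    mean_regen_limbs_per_crab = mean(a$n_regenerating),
    sd_regen_limbs_per_crab = sd(a$n_regenerating),
    mean_regen_mass_mg = 1000 * mean(a$regen_mass_total_g),
    sd_regen_mass_mg = 1000 * sd(a$regen_mass_total_g)
  )
  list(per_limb = per_limb, totals = totals)
}
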