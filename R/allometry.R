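#' Fit a per-limb power-law mass--size relationship
#'
#' Fits `mass = a * CW^b` to the limbs physically present at position
#' `limb_id` (observed status `intact` -- which includes partially
#' regenerated limbs, the very signal detected downstream; buds and missing
#' limbs are excluded). The fit minimizes squared error on the mass scale by
#' Gauss-Newton NLS, started from ordinary least squares on
#' `log(mass) ~ log(CW)`; if the NLS step fails (e.g. a perfect fit with
#' zero residual), a direct Nelder-Mead minimization of the same sum of
#' squares is used as fallback. Residuals (observed minus predicted mass,
#' grams) are attached for every limb used.
#'
#' @param crabs Crab table as produced by [generate_population()] or
#'   [read_crab_table()].
#' @param limb_id Limb position, 1--10 (1 = right claw, clockwise to
#'   10 = left claw).
#' @param min_n Minimum number of present limbs required (default 10).
#' @param exclude_crab_ids Crabs whose limb at this position is left out of
#'   the fit (used by the iterative refit mode of
#'   [assess_regeneration()]); residuals are still computed for them.
#' @return An `allometric_fit`: list with `limb_id`, `a`, `b`,
#'   `n_limbs_used`, `residuals` (named by `crab_id`), `residual_sd`,
#'   `converged`, and the `crab_id`/`cw`/`mass` vectors used.
#' @export
fit_limb_allometry <- function(crabs, limb_id, min_n = 10,
                               exclude_crab_ids = NULL) {
  stopifnot(limb_id %in% 1:10)
  status <- crabs[[limb_status_col(limb_id)]]
  mass <- crabs[[limb_mass_col(limb_id)]]
  cw <- crabs$carapace_width_mm
  present <- status == "intact" & !is.na(mass) & !is.na(cw)
  use <- present & !crabs$crab_id %in% exclude_crab_ids
  if (sum(use) < min_n)
    stop("fit_limb_allometry: limb ", limb_id, " has only ", sum(use),
         " present limbs (need >= ", min_n, ")")
  if (any(cw[use] <= 0)) stop("carapace width must be positive")
  if (any(mass[use] <= 0)) stop("intact limb masses must be positive")

  fit <- power_law_nls(cw[use], mass[use])
  res <- mass[present] - fit$a * cw[present]^fit$b
  out <- list(
    limb_id = limb_id, a = fit$a, b = fit$b,
    n_limbs_used = sum(use),
    residuals = setNames(res, crabs$crab_id[present]),
    residual_sd = sd(mass[use] - fit$a * cw[use]^fit$b),
    converged = fit$converged,
    crab_id = crabs$crab_id[present], cw = cw[present],
    mass = mass[present]
  )
  class(out) <- "allometric_fit"
  out
}

# Mass-scale NLS for y = a * x^b with log-log OLS start and optim fallback.
power_law_nls <- function(x, y, max_iter = 500, tol = 1e-8) {
  ols <- lm(log(y) ~ log(x))
  start <- list(a = exp(unname(coef(ols)[1])), b = unname(coef(ols)[2]))
  ss <- function(p) sum((y - exp(p[1]) * x^p[2])^2)
  fit <- tryCatch({
    # scaleOffset rescues the relative-offset convergence test on
    # (near-)zero-residual data, where it is otherwise undefined.
    m <- suppressWarnings(
      nls(y ~ a * x^b, start = start,
          control = nls.control(maxiter = max_iter, tol = tol,
                                minFactor = 1e-12, warnOnly = TRUE,
                                scaleOffset = 1)))
    list(a = unname(coef(m)["a"]), b = unname(coef(m)["b"]),
         converged = m$convInfo$isConv)
  }, error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    # Polish the log-log start by direct search on the same objective.
    p0 <- c(log(start$a), start$b)
    op <- optim(p0, ss, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
    cand <- list(a = exp(op$par[1]), b = op$par[2],
                 converged = op$convergence == 0)
    if (is.null(fit) || ss(c(log(cand$a), cand$b)) <=
        ss(c(log(fit$a), fit$b))) fit <- cand
  }
  # An essentially perfect fit is converged whatever the iteration said.
  if (!fit$converged &&
      ss(c(log(fit$a), fit$b)) <= 1e-16 * sum(y^2)) fit$converged <- TRUE
  fit
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("Limb %d allometry: mass = %.4g * CW^%.4f (n = %d, %s)\n",
              x$limb_id, x$a, x$b, x$n_limbs_used,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Fit allometries for all ten limbs
#'
#' @inheritParams fit_limb_allometry
#' @return A list of ten `allometric_fit` objects, indexed by limb.
#' @export
fit_all_limb_allometry <- function(crabs, min_n = 10) {
  lapply(1:10, function(l) fit_limb_allometry(crabs, l, min_n = min_n))
}

#' Summarize per-limb fits as a table
#'
#' @param fits List of `allometric_fit` objects.
#' @return Data frame: `limb_id`, `a`, `b`, `n`, `residual_sd`, `converged`.
#' @export
allometry_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(limb_id = f$limb_id, a = f$a, b = f$b, n = f$n_limbs_used,
               residual_sd = f$residual_sd, converged = f$converged)))
}

#' Predict limb mass from a fitted allometry
#'
#' Evaluates `a * cw^b`. Refuses an unconverged fit: downstream residual
#' classification would otherwise inherit a meaningless baseline.
#'
#' @param fit An `allometric_fit`.
#' @param cw Carapace width(s), mm, positive.
#' @return Predicted dry mass (g).
#' @export
predict_limb_mass <- function(fit, cw) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (!isTRUE(fit$converged))
    stop("predict_limb_mass: fit for limb ", fit$limb_id,
         " did not converge")
  if (any(cw <= 0)) stop("cw must be positive")
  fit$a * cw^fit$b
}

#' Energy--mass calibration of limb tissue
#'
#' Ordinary least-squares regression of bomb-calorimetry energy content (kJ)
#' on limb dry mass (g). A linear relationship justifies using regenerated
#' limb mass as a proxy for the energy already allocated to regeneration.
#'
#' @param leg_masses Dry masses (g).
#' @param energies Energy contents (kJ).
#' @return An `energy_calibration`: `slope` (kJ/g), `slope_se`, `intercept`,
#'   `t_statistic`, `r_squared`, `n`.
#' @export
fit_energy_mass_regression <- function(leg_masses, energies) {
  if (length(leg_masses) != length(energies))
    stop("leg_masses and energies must have equal length")
  if (length(leg_masses) < 3) stop("need at least 3 paired observations")
  if (var(leg_masses) == 0)
    stop("leg masses are constant: slope undefined")
  m <- lm(energies ~ leg_masses)
  sm <- summary(m)
  out <- list(
    slope = unname(coef(m)[2]),
    slope_se = sm$coefficients[2, 2],
    intercept = unname(coef(m)[1]),
    t_statistic = sm$coefficients[2, 3],
    r_squared = sm$r.squared,
    n = length(leg_masses)
  )
  class(out) <- "energy_calibration"
  out
}

#' @export
print.energy_calibration <- function(x, ...) {
  cat(sprintf(
    "Energy ~ mass: %.2f +/- %.2f kJ/g (t = %.2f, R^2 = %.3f, n = %d)\n",
    x$slope, x$slope_se, x$t_statistic, x$r_squared, x$n))
  invisible(x)
}
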