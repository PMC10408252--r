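# Shared fixtures, all built in code.

# A handcrafted single-crab row with explicit limb states and masses.
crab_row <- function(crab_id = "X001", cw = 20, julian = 150, site = "A",
                     statuses = rep("intact", 10), masses = NULL,
                     ovary = 0.2, hep = 0.25, stomach = 0.05, body = 2.0) {
  if (is.null(masses))
    masses <- ifelse(statuses == "intact", 2e-5 * cw^3, NA_real_)
  row <- data.frame(crab_id = crab_id, site = site, julian_day = julian,
                    carapace_width_mm = cw, stringsAsFactors = FALSE)
  for (l in 1:10) row[[sprintf("limb%02d_status", l)]] <- statuses[l]
  for (l in 1:10) row[[sprintf("limb%02d_mass_g", l)]] <- masses[l]
  row$ovary_mass_g <- ovary
  row$hepatopancreas_mass_g <- hep
  row$stomach_mass_g <- stomach
  row$body_rest_mass_g <- body
  row
}

crab_table <- function(...) do.call(rbind, list(...))

# A minimal regen_assessment for summary-level tests that do not need the
# detection machinery.
manual_assessment <- function(crabs, flags) {
  status <- as.matrix(crabs[, sprintf("limb%02d_status", 1:10)])
  mass <- as.matrix(crabs[, sprintf("limb%02d_mass_g", 1:10)])
  n <- nrow(crabs)
  regen_mass <- vapply(seq_len(n), function(i)
    sum(mass[i, flags[i, ] & status[i, ] == "intact"], na.rm = TRUE),
    numeric(1))
  structure(list(
    flags = flags,
    assessment = data.frame(
      crab_id = crabs$crab_id,
      n_missing = rowSums(status == "missing"),
      n_buds = rowSums(status == "bud"),
      n_regenerating = rowSums(flags),
      regen_mass_total_g = regen_mass
    )
  ), class = "regen_assessment")
}

# A converged allometric fit object with known coefficients.
manual_fit <- function(a, b, limb_id = 1, converged = TRUE) {
  structure(list(limb_id = limb_id, a = a, b = b, n_limbs_used = 0,
                 residuals = numeric(0), residual_sd = NA_real_,
                 converged = converged),
            class = "allometric_fit")
}

expect_file_identical <- function(f1, f2) {
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
}
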