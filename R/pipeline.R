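#' Validate and clean an input crab table
#'
#' Canonical schema: `crab_id`, `site`, `julian_day`, `carapace_width_mm`,
#' `limb01_status` ... `limb10_status`, `limb01_mass_g` ... `limb10_mass_g`,
#' `ovary_mass_g`, `hepatopancreas_mass_g`, `stomach_mass_g`,
#' `body_rest_mass_g`. Status strings are normalized (case-insensitive;
#' `absent` is accepted for `missing`, `limb_bud`/`bud` for `bud`,
#' `present` for `intact`). Rows missing any organ mass or the carapace
#' width are dropped and logged, mirroring field practice of discarding
#' crabs with incomplete tissue samples. Hard errors: unknown status token,
#' negative mass, duplicate `crab_id`, missing columns. A unit sanity check
#' warns when a limb outweighs the rest of the body.
#'
#' @param crabs Raw data frame.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the input's column names (adapter for external
#'   datasets), e.g. `c(carapace_width_mm = "cw")`.
#' @return List: `crabs` (clean table), `discarded` (data frame of dropped
#'   rows with a `reason` column), `n_input`, `n_analyzed`, `n_discarded`.
#' @export
validate_input <- function(crabs, column_map = NULL) {
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(crabs))
        stop("validate_input: mapped column `", src, "` not in input")
      names(crabs)[names(crabs) == src] <- canon
    }
  }
  organ_cols <- c("ovary_mass_g", "hepatopancreas_mass_g", "stomach_mass_g",
                  "body_rest_mass_g")
  need <- c("crab_id", "julian_day", "carapace_width_mm",
            limb_status_col(1:10), limb_mass_col(1:10), organ_cols)
  miss <- setdiff(need, names(crabs))
  if (length(miss))
    stop("validate_input: missing column(s): ", paste(miss, collapse = ", "))
  if (!"site" %in% names(crabs)) crabs$site <- "unknown"

  if (anyDuplicated(crabs$crab_id))
    stop("validate_input: duplicate crab_id: ",
         paste(unique(crabs$crab_id[duplicated(crabs$crab_id)]),
               collapse = ", "))

  norm <- c(intact = "intact", present = "intact",
            missing = "missing", absent = "missing",
            bud = "bud", limb_bud = "bud", limbbud = "bud")
  for (l in 1:10) {
    col <- limb_status_col(l)
    tok <- tolower(trimws(crabs[[col]]))
    unknown <- !tok %in% names(norm)
    if (any(unknown))
      stop("validate_input: unknown limb status token(s) in ", col, ": ",
           paste(unique(crabs[[col]][unknown]), collapse = ", "),
           " (row ", paste(which(unknown)[1]), ")")
    crabs[[col]] <- unname(norm[tok])
  }

  mass_cols <- c(limb_mass_col(1:10), organ_cols, "carapace_width_mm")
  for (col in mass_cols) {
    bad <- !is.na(crabs[[col]]) & crabs[[col]] < 0
    if (any(bad))
      stop("validate_input: negative value in ", col, " (row ",
           which(bad)[1], ")")
  }

  incomplete <- rowSums(is.na(crabs[, organ_cols])) > 0 |
    is.na(crabs$carapace_width_mm)
  discarded <- crabs[incomplete, , drop = FALSE]
  if (nrow(discarded) > 0)
    discarded$reason <- vapply(seq_len(nrow(discarded)), function(i) {
      row <- discarded[i, ]
      bad <- c(organ_cols, "carapace_width_mm")[
        is.na(unlist(row[c(organ_cols, "carapace_width_mm")]))]
      paste("missing", paste(bad, collapse = "+"))
    }, "")
  clean <- crabs[!incomplete, , drop = FALSE]

  limb_mass <- as.matrix(clean[, limb_mass_col(1:10)])
  heavy <- rowSums(limb_mass > clean$body_rest_mass_g, na.rm = TRUE) > 0
  if (any(heavy))
    warning("validate_input: ", sum(heavy), " crab(s) have a limb ",
            "outweighing the rest of the body; check units")

  list(crabs = clean, discarded = discarded,
       n_input = nrow(crabs), n_analyzed = nrow(clean),
       n_discarded = nrow(discarded))
}

#' Run the full analysis pipeline
#'
#' validate -> allometry -> detection -> injury summary -> trade-off models
#' -> report. All intermediate tables, a JSON run manifest and a log are
#' written to `out_dir`. With identical inputs and seed the CSV outputs are
#' byte-identical across runs.
#'
#' @param input Either a crab data frame / CSV path, or a
#'   [generator_config()] (the population is then simulated first).
#' @param out_dir Output directory. Created if absent; refuses to reuse an
#'   existing non-empty directory unless `overwrite = TRUE`.
#' @param spec A [cutoff_spec()].
#' @param responses Organs to model (subset of stomach, ovary,
#'   hepatopancreas, body). `body` uses corrected body mass as response.
#' @param squared_bud_for Organs for which a squared bud term is also
#'   fitted and compared by AIC (default: the gut and storage organs, where
#'   unimodal bud effects are biologically plausible).
#' @param column_map Optional column mapping for [validate_input()].
#' @param cyclic_season Passed to [fit_tradeoff_gam()].
#' @param k Smooth basis dimension.
#' @param plots If `TRUE`, also write PNG residual figures (requires a
#'   working png device).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the manifest, assessment, summary and
#'   model results.
#' @export
run_pipeline <- function(input, out_dir,
                         spec = cutoff_spec(),
                         responses = ORGANS,
                         squared_bud_for = c("stomach", "hepatopancreas"),
                         column_map = NULL, cyclic_season = FALSE, k = 10,
                         plots = FALSE, overwrite = FALSE) {
  stopifnot(all(responses %in% ORGANS))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("run_pipeline: output directory ", out_dir,
         " is not empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  logit <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  manifest <- list(package_version = as.character(packageVersion("regenscan")),
                   cutoff_spec = unclass(spec), stages = list())
  fail <- function(stage, e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, log_path)
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- input / simulate ---
  truth <- NULL
  crabs_raw <- tryCatch({
    if (inherits(input, "generator_config")) {
      logit("simulate", sprintf("generating %d crabs (seed %d)",
                                input$n_crabs, input$seed))
      pop <- generate_population(input)
      write_population(pop, file.path(out_dir, "population.csv"),
                       truth_path = file.path(out_dir, "truth_limbs.csv"))
      write_generator_config(input, file.path(out_dir, "config.json"))
      manifest$config_hash <- unname(tools::md5sum(
        file.path(out_dir, "config.json")))
      manifest$seed <- input$seed
      truth <- pop$truth
      pop$crabs
    } else if (is.character(input)) {
      logit("input", paste("reading", input))
      read_crab_table(input)
    } else as.data.frame(input)
  }, error = function(e) fail("input", e))

  # --- validate ---
  val <- tryCatch(validate_input(crabs_raw, column_map = column_map),
                  error = function(e) fail("validate", e))
  logit("validate", sprintf("%d rows in, %d analyzed, %d discarded",
                            val$n_input, val$n_analyzed, val$n_discarded))
  manifest$stages$validate <- list(rows_in = val$n_input,
                                   analyzed = val$n_analyzed,
                                   discarded = val$n_discarded)
  if (val$n_discarded > 0)
    write.csv(val$discarded, file.path(out_dir, "discarded.csv"),
              row.names = FALSE)
  crabs <- val$crabs

  # --- allometry ---
  fits <- tryCatch(fit_all_limb_allometry(crabs),
                   error = function(e) fail("allometry", e))
  ft <- allometry_table(fits)
  write.csv(format_numeric(ft), file.path(out_dir, "allometry_fits.csv"),
            row.names = FALSE, quote = FALSE)
  logit("allometry", sprintf("10 limb fits, b in [%.2f, %.2f]",
                             min(ft$b), max(ft$b)))

  # --- detection ---
  assess <- tryCatch(assess_regeneration(crabs, fits, spec),
                     error = function(e) fail("detect", e))
  write.csv(format_numeric(assess$assessment),
            file.path(out_dir, "assessments.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(format_numeric(assess$cutoffs),
            file.path(out_dir, "cutoffs.csv"),
            row.names = FALSE, quote = FALSE)
  inj <- summarize_injury(assess, crabs)
  write.csv(inj$per_limb, file.path(out_dir, "injury_by_limb.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(format_numeric(data.frame(metric = names(inj$totals),
                       value = unlist(inj$totals, use.names = FALSE))),
            file.path(out_dir, "injury_totals.csv"),
            row.names = FALSE, quote = FALSE)
  logit("detect", sprintf("%d regenerating limbs flagged",
                          inj$totals$n_regenerating))
  manifest$stages$detect <- list(
    n_regenerating = inj$totals$n_regenerating,
    n_missing_total = inj$totals$n_missing_total)

  # --- models ---
  a <- assess$assessment
  budr <- tryCatch(residualize_buds(a$n_buds, a$n_missing),
                   error = function(e) fail("model", e))
  results <- list()
  comparison <- NULL
  for (org in responses) {
    y <- if (org == "body") a$corrected_body_mass_g else a[[organ_column(org)]]
    res <- tryCatch({
      lin <- fit_tradeoff_gam(y, a, budr$residuals, k = k,
                              cyclic_season = cyclic_season,
                              response_name = org)
      if (org %in% squared_bud_for) {
        quad <- fit_tradeoff_gam(y, a, budr$residuals,
                                 squared_terms = "bud_resid", k = k,
                                 cyclic_season = cyclic_season,
                                 response_name = org)
        select_model(lin, quad)
      } else {
        lin$delta_aic <- NA_real_
        lin$rejected_label <- NA_character_
        lin
      }
    }, error = function(e) fail("model", e))
    results[[org]] <- res
    write.csv(format_numeric(res$parametric),
              file.path(out_dir, sprintf("model_%s.csv", org)),
              row.names = FALSE, quote = FALSE)
    comparison <- rbind(comparison, data.frame(
      response = org, chosen = res$label, aic = res$aic,
      delta_aic = res$delta_aic,
      deviance_explained = res$deviance_explained, n = res$n))
    logit("model", sprintf("%s: %s, AIC %.1f, %.1f%% deviance", org,
                           res$label, res$aic,
                           100 * res$deviance_explained))
  }
  write.csv(format_numeric(comparison),
            file.path(out_dir, "model_comparison.csv"),
            row.names = FALSE, quote = FALSE)
  manifest$stages$model <- list(responses = responses,
                                chosen = comparison$chosen)

  if (plots)
    tryCatch(write_residual_plots(a, responses, out_dir, k = k,
                                  cyclic_season = cyclic_season),
             error = function(e) logit("plots",
                                       paste("skipped:",
                                             conditionMessage(e))))

  # --- recovery report against truth, if simulated ---
  recov <- NULL
  if (!is.null(truth)) {
    recov <- do.call(rbind, lapply(responses, function(org) {
      r <- recovery_report(results[[org]], truth, org)
      cbind(organ = org, r)
    }))
    write.csv(format_numeric(recov), file.path(out_dir, "recovery.csv"),
              row.names = FALSE, quote = FALSE)
  }

  manifest$completed <- TRUE
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(manifest = manifest, assessment = assess,
                 injury_summary = inj, models = results,
                 comparison = comparison, recovery = recov,
                 bud_residualization = budr))
}

# Figure-style outputs: boxplots of covariate-adjusted Pearson residuals
# against injury counts, scatter against the regeneration index.
write_residual_plots <- function(a, responses, out_dir, k = 10,
                                 cyclic_season = FALSE) {
  for (org in responses) {
    y <- if (org == "body") a$corrected_body_mass_g else a[[organ_column(org)]]
    pr <- plotting_residuals(y, a$carapace_width_mm, a$julian_day, k = k,
                             cyclic_season = cyclic_season)
    grDevices::png(file.path(out_dir, sprintf("fig_%s.png", org)),
                   width = 1500, height = 500, res = 120)
    graphics::par(mfrow = c(1, 3))
    graphics::boxplot(pr ~ a$n_missing, xlab = "limbs missing",
                      ylab = "residual mass (g)", main = org)
    graphics::abline(h = 0, lty = 2)
    graphics::boxplot(pr ~ a$n_buds, xlab = "limb buds",
                      ylab = "residual mass (g)")
    graphics::abline(h = 0, lty = 2)
    graphics::plot(a$regen_mass_total_g, pr,
                   xlab = "regenerated limb mass (g)",
                   ylab = "residual mass (g)")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  }
}
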