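#' Descriptive cohort characteristics table
#'
#' Summarizes a cohort the way clinical baseline tables are reported: mean
#' (SD) for continuous variables, n (%) for categorical ones, including the
#' diagnosis groups, APOE e4 allele counts and PET status. Absent category
#' levels are reported with a zero count.
#'
#' @param cohort A cohort data frame.
#' @return A `data.frame` with columns `variable`, `level`, `value`
#'   (formatted string), `mean`/`sd` or `n`/`pct` (numeric).
#' @examples
#' table_one(generate_cohort(generator_config(seed = 1)))
#' @export
table_one <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop_config("cohort must be a non-empty data frame")
  n <- nrow(cohort)
  rows <- list()
  add_cont <- function(var, label) {
    m <- mean(cohort[[var]]); s <- stats::sd(cohort[[var]])
    rows[[length(rows) + 1]] <<- data.frame(
      variable = label, level = "", value = sprintf("%.2f (%.2f)", m, s),
      mean = m, sd = s, n = NA_real_, pct = NA_real_)
  }
  add_cat <- function(var, label, levels) {
    for (lv in levels) {
      cnt <- sum(cohort[[var]] == lv)
      rows[[length(rows) + 1]] <<- data.frame(
        variable = label, level = as.character(lv),
        value = sprintf("%d (%.1f)", cnt, 100 * cnt / n),
        mean = NA_real_, sd = NA_real_, n = cnt, pct = 100 * cnt / n)
    }
  }
  rows[[1]] <- data.frame(variable = "n", level = "", value = as.character(n),
                          mean = NA_real_, sd = NA_real_, n = n, pct = NA_real_)
  add_cat("group", "Diagnosis", c("CN", "SCD"))
  add_cont("age", "Age")
  add_cat("sex", "Sex", c("male", "female"))
  add_cont("education", "Education")
  add_cat("apoe_e4_count", "APOE e4 alleles", 0:2)
  add_cont("pet_suvr", "Abeta PET, SUVR")
  add_cat("pet_status", "Abeta PET, status", c(0, 1))
  add_cont("plasma_ab4240", "Plasma Abeta42/Abeta40")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pre-screening simulation pipeline
#'
#' Generates (or loads) a cohort, fits the risk model, sweeps relative and/or
#' absolute invitation thresholds with bootstrap uncertainty, converts the
#' test counts into cost savings across PET-to-plasma cost ratios, and writes
#' all artifacts into `out_dir`: `cohort.csv`, `model.json`,
#' `screening_<mode>.csv`, `costs.csv`, `summary.md`, `run_config.json` and
#' (optionally) one figure per mode with the yield, test-count and cost
#' panels. Identical configuration and seed produce byte-identical CSVs.
#'
#' @param config A [generator_config()] (its `seed` is combined with `seed`);
#'   alternatively pass a ready-made cohort via `cohort`.
#' @param cohort Optional cohort data frame; when supplied `config` is only
#'   used for metadata.
#' @param variant Model variant.
#' @param modes Threshold modes to sweep.
#' @param grid Threshold grid.
#' @param n_target PET-positive recruitment target.
#' @param B Bootstrap replicates.
#' @param ratios PET-to-plasma cost ratios.
#' @param seed Master RNG seed for generation and bootstraps.
#' @param out_dir Output directory (created if needed).
#' @param make_plots Write the figure files (skipped quietly if the graphics
#'   device is unavailable).
#' @return Invisibly, a list with the cohort, model, per-mode screening and
#'   cost tables, and `out_dir`.
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL,
                         variant = "full",
                         modes = c("relative", "absolute"),
                         grid = seq(0, 0.90, by = 0.05),
                         n_target = 500, B = 1000, ratios = c(4, 8, 16),
                         seed = 1L, out_dir = tempfile("petscreen_run_"),
                         make_plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(fmt, ...) message(sprintf(paste0("[petscreen] ", fmt), ...))

  if (is.null(cohort)) {
    config$seed <- seed
    stage("generating cohort (n = %d, seed = %d)", as.integer(config$n), seed)
    cohort <- generate_cohort(config)
  } else {
    cohort <- validate_cohort(cohort)
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  stage("fitting '%s' risk model", variant)
  model <- fit_risk_model(cohort, variant = variant)
  auc_in <- auc(predict_risk(model, cohort), cohort$pet_status)

  cfg_json <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(list(
    generator = unclass(config), variant = variant, modes = modes,
    grid = grid, n_target = n_target, B = B, ratios = ratios, seed = seed),
    cfg_json, auto_unbox = TRUE, digits = NA, null = "null")
  config_hash <- unname(tools::md5sum(cfg_json))

  jsonlite::write_json(list(
    variant = model$variant,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    odds_ratios = as.list(exp(model$coefficients)),
    standardization = lapply(model$standardization, as.list),
    convergence = model$convergence,
    n = model$n, n_pos = model$n_pos, auc_in_sample = auc_in,
    seed = seed, config_hash = config_hash),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)

  screenings <- list()
  costs <- list()
  for (mode in modes) {
    stage("sweeping %s thresholds (B = %d)", mode, B)
    sc <- screen_sweep(cohort, variant = variant, mode = mode, grid = grid,
                       n_target = n_target, B = B, seed = seed)
    if (B > 0 && !is.null(attr(sc, "replicates")))
      stage("%s mode: %d bootstrap resamples discarded", mode,
            attr(sc, "replicates")$discarded)
    utils::write.csv(cbind(as.data.frame(sc), seed = seed,
                           config_hash = config_hash),
                     file.path(out_dir, sprintf("screening_%s.csv", mode)),
                     row.names = FALSE)
    screenings[[mode]] <- sc
    costs[[mode]] <- cost_sweep(sc, ratios = ratios)
  }
  cost_all <- do.call(rbind, lapply(costs, as.data.frame))
  utils::write.csv(cbind(cost_all, seed = seed, config_hash = config_hash),
                   file.path(out_dir, "costs.csv"), row.names = FALSE)

  write_summary_md(file.path(out_dir, "summary.md"), cohort, model, auc_in,
                   screenings, costs, n_target, B, seed, config_hash)

  if (make_plots) {
    for (mode in names(screenings)) {
      tryCatch(
        save_mode_figure(screenings[[mode]], costs[[mode]],
                         file.path(out_dir, sprintf("figure_%s.png", mode))),
        error = function(e) stage("plotting skipped (%s)", conditionMessage(e)))
    }
  }
  stage("done: %s", out_dir)
  invisible(list(cohort = cohort, model = model, screenings = screenings,
                 costs = costs, out_dir = out_dir))
}

write_summary_md <- function(path, cohort, model, auc_in, screenings, costs,
                             n_target, B, seed, config_hash) {
  lines <- c(
    "# Pre-screening simulation summary", "",
    sprintf("- seed: %d; bootstrap B: %d; config hash: %s", seed, B, config_hash),
    sprintf("- cohort: n = %d, PET+ prevalence %.1f%%", nrow(cohort),
            100 * mean(cohort$pet_status)),
    sprintf("- model '%s': in-sample AUC %.3f; ORs: %s", model$variant, auc_in,
            paste(sprintf("%s = %.2f", names(model$coefficients),
                          exp(model$coefficients)), collapse = ", ")),
    "")
  for (mode in names(screenings)) {
    sc <- screenings[[mode]]
    lines <- c(lines, sprintf("## %s risk approach", mode), "")
    for (q in c(0.25, 0.5, 0.75)) {
      i <- which(abs(sc$threshold - q) < 1e-9)
      if (!length(i) || is.na(sc$ppv[i])) next
      lines <- c(lines, sprintf(
        paste0("- threshold %d%%: PET+ yield %.1f%% [CI (%.1f, %.1f); P = %.4g], ",
               "%d PET scans and %d plasma tests to recruit %d PET+ participants"),
        round(100 * q), 100 * sc$ppv_boot[i], 100 * sc$ppv_lo[i],
        100 * sc$ppv_hi[i], sc$p_vs_none[i],
        round(sc$n_pet_boot[i]), round(sc$n_plasma_boot[i]), n_target))
      cr <- costs[[mode]]
      for (r in unique(cr$ratio)) {
        j <- which(cr$threshold == sc$threshold[i] & cr$ratio == r)
        if (length(j) && !is.na(cr$delta_boot[j]))
          lines <- c(lines, sprintf(
            "    - %gx cost ratio: delta-cost = %.1f%% (%.1f, %.1f), P = %.4g",
            r, cr$delta_boot[j], cr$delta_lo[j], cr$delta_hi[j], cr$p_value[j]))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
}
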