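#' Per-organ, per-arm descriptive summary of agreement metrics
#'
#' Mean and standard deviation (n - 1 denominator) of DSC and HD95 per
#' (organ, imaging system), over all non-missing (patient, observer) rows.
#' Empty strata are emitted as rows of `NA` rather than dropped.
#'
#' @param metric_table output of [metrics_for_cohort()].
#' @return `data.frame` with `organ`, `imaging_system`, `n`, `dsc_mean`,
#'   `dsc_sd`, `hd95_mean`, `hd95_sd`.
#' @export
summarize_descriptives <- function(metric_table) {
  stopifnot(is.data.frame(metric_table), nrow(metric_table) > 0)
  organs <- unique(metric_table$organ)
  systems <- unique(metric_table$imaging_system)
  grid <- expand.grid(organ = organs, imaging_system = systems,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- metric_table[metric_table$organ == grid$organ[i] &
                          metric_table$imaging_system == grid$imaging_system[i] &
                          is.finite(metric_table$dsc), , drop = FALSE]
    n <- nrow(sub)
    data.frame(organ = grid$organ[i], imaging_system = grid$imaging_system[i],
               n = n,
               dsc_mean = if (n) mean(sub$dsc) else NA_real_,
               dsc_sd = if (n > 1) sd(sub$dsc) else NA_real_,
               hd95_mean = if (n) mean(sub$hd95) else NA_real_,
               hd95_sd = if (n > 1) sd(sub$hd95) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-patient correction-time pairs: total over organs within (patient,
# observer, arm), then averaged over observers, one pair of columns per arm.
correction_time_pairs <- function(metadata, systems) {
  ok <- metadata[!metadata$missing & is.finite(metadata$correction_time_s), ]
  tot <- stats::aggregate(correction_time_s ~ patient_id + observer_id + imaging_system,
                          data = ok, FUN = sum)
  avg <- stats::aggregate(correction_time_s ~ patient_id + imaging_system,
                          data = tot, FUN = mean)
  wide <- stats::reshape(avg, idvar = "patient_id", timevar = "imaging_system",
                         direction = "wide")
  names(wide) <- sub("^correction_time_s\\.", "", names(wide))
  wide[order(wide$patient_id), c("patient_id", systems)]
}

# Per-patient confidence pairs for one organ: mean over observers per arm.
confidence_pairs <- function(metadata, organ, systems) {
  ok <- metadata[!metadata$missing & metadata$organ == organ &
                   is.finite(metadata$confidence), ]
  avg <- stats::aggregate(confidence ~ patient_id + imaging_system,
                          data = ok, FUN = mean)
  wide <- stats::reshape(avg, idvar = "patient_id", timevar = "imaging_system",
                         direction = "wide")
  names(wide) <- sub("^confidence\\.", "", names(wide))
  wide[order(wide$patient_id), c("patient_id", systems)]
}

fmt_mmss <- function(seconds) {
  sprintf("%d:%02d", as.integer(seconds) %/% 60L, as.integer(round(seconds)) %% 60L)
}

#' Run the whole evaluation pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> metrics -> analyze -> report: generates the
#' cohort, computes DSC/HD95 for every delineation, fits the crossed
#' random-intercepts model per organ and metric, estimates the
#' variance-ratio ICC per arm with stratified bootstrap confidence intervals
#' and Welch comparisons, runs the workflow endpoints (paired t-test on
#' correction times, Wilcoxon signed-rank on confidence per organ), applies
#' the Bonferroni family correction, and writes all tables as CSV plus a
#' human-readable report. Identical config (and seed) produces byte-identical
#' outputs.
#'
#' @param config a [cohort_config()], or the path of a YAML/JSON config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @param B optional override of `config$bootstrap_B`.
#' @param alpha family-wise significance level.
#' @param write_nifti also export every mask as NIfTI (slow; off by default).
#' @return object of class `study_report` (invisibly the same tables that
#'   were written): `descriptives`, `model_fits`, `icc`, `confidence`,
#'   `time_comparison`, `alpha_per_test`, `m_tests`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, B = NULL,
                         alpha = 0.05, write_nifti = FALSE) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) { config$seed <- as.integer(seed) }
  if (!is.null(B)) config$bootstrap_B <- as.integer(B)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  fail <- function(stage, e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  organs <- config$organs
  systems <- config$imaging_systems
  hp <- systems[1]; conv <- systems[2]

  # --- simulate ------------------------------------------------------------
  cohort <- tryCatch(generate_cohort(config), error = function(e) fail("simulate", e))
  metadata <- cohort_metadata(cohort)
  emit(metadata, "metadata.csv")
  if (write_nifti) export_cohort_nifti(cohort, file.path(out_dir, "masks"))

  # --- metrics -------------------------------------------------------------
  metrics <- tryCatch(suppressMessages(metrics_for_cohort(cohort)),
                      error = function(e) fail("metrics", e))
  emit(metrics, "metrics.csv")
  descr <- summarize_descriptives(metrics)
  emit(descr, "descriptives.csv")

  # --- analyze: crossed model per organ x metric ---------------------------
  m_tests <- 5L * length(organs) + 1L
  alpha_per_test <- bonferroni_level(alpha, m_tests)
  fits <- tryCatch({
    do.call(rbind, lapply(organs, function(org) {
      do.call(rbind, lapply(c("dsc", "hd95"), function(resp) {
        f <- fit_crossed_model(metrics, response = resp, organ = org,
                               reference = conv)
        data.frame(organ = org, metric = resp,
                   coefficient = f$beta1, se = f$se_beta1,
                   df = f$df, p_value = f$p_value,
                   sigma2_patient = f$sigma2_patient,
                   sigma2_observer = f$sigma2_observer,
                   sigma2_residual = f$sigma2_residual,
                   converged = f$converged,
                   significant = !is.na(f$p_value) & f$p_value < alpha_per_test,
                   stringsAsFactors = FALSE)
      }))
    }))
  }, error = function(e) fail("model", e))
  emit(fits, "model_fits.csv")

  # --- analyze: ICC per organ x metric x arm -------------------------------
  icc_tab <- tryCatch({
    combo <- 0L
    do.call(rbind, lapply(organs, function(org) {
      do.call(rbind, lapply(c("dsc", "hd95"), function(resp) {
        combo <<- combo + 1L
        sub <- metrics[metrics$organ == org & is.finite(metrics[[resp]]), ]
        tab_hp <- sub[sub$imaging_system == hp, ]
        tab_cv <- sub[sub$imaging_system == conv, ]
        pt_hp <- icc_point(tab_hp, response = resp)
        pt_cv <- icc_point(tab_cv, response = resp)
        b_hp <- stratified_bootstrap_icc(tab_hp, B = config$bootstrap_B,
                                         seed = config$seed + 1000L + 2L * combo,
                                         response = resp)
        b_cv <- stratified_bootstrap_icc(tab_cv, B = config$bootstrap_B,
                                         seed = config$seed + 1001L + 2L * combo,
                                         response = resp)
        cmp <- compare_icc(b_hp, b_cv, icc_hp = pt_hp$icc, icc_conv = pt_cv$icc)
        data.frame(organ = org, metric = resp,
                   icc_hp = pt_hp$icc, icc_conv = pt_cv$icc,
                   boot_mean_hp = cmp$boot_mean_hp,
                   boot_mean_conv = cmp$boot_mean_conv,
                   delta_ci_lower = cmp$delta_ci[1],
                   delta_ci_upper = cmp$delta_ci[2],
                   welch_t = cmp$welch_t, p_value = cmp$p_value,
                   B = cmp$B,
                   significant = !is.na(cmp$p_value) & cmp$p_value < alpha_per_test,
                   stringsAsFactors = FALSE)
      }))
    }))
  }, error = function(e) fail("icc", e))
  emit(icc_tab, "icc.csv")

  # --- analyze: workflow endpoints -----------------------------------------
  wf <- tryCatch({
    tp <- correction_time_pairs(metadata, systems)
    tt <- paired_ttest(tp[[hp]], tp[[conv]])
    time_tab <- data.frame(
      mean_hp_s = mean(tp[[hp]]), sd_hp_s = sd(tp[[hp]]),
      mean_conv_s = mean(tp[[conv]]), sd_conv_s = sd(tp[[conv]]),
      t = tt$statistic, df = tt$df, p_value = tt$p_value, n = tt$n,
      significant = !is.na(tt$p_value) & tt$p_value < alpha_per_test)
    conf_tab <- do.call(rbind, lapply(organs, function(org) {
      sub <- metadata[!metadata$missing & metadata$organ == org, ]
      cp <- confidence_pairs(metadata, org, systems)
      wt <- wilcoxon_signed_rank(cp[[hp]], cp[[conv]])
      data.frame(organ = org,
                 mean_hp = mean(sub$confidence[sub$imaging_system == hp]),
                 sd_hp = sd(sub$confidence[sub$imaging_system == hp]),
                 mean_conv = mean(sub$confidence[sub$imaging_system == conv]),
                 sd_conv = sd(sub$confidence[sub$imaging_system == conv]),
                 W = wt$statistic, p_value = wt$p_value, n_pairs = wt$n,
                 significant = !is.na(wt$p_value) & wt$p_value < alpha_per_test,
                 stringsAsFactors = FALSE)
    }))
    list(time = time_tab, confidence = conf_tab)
  }, error = function(e) fail("workflow", e))
  emit(wf$time, "time_comparison.csv")
  emit(wf$confidence, "confidence.csv")

  mult <- data.frame(
    family = c("autosegmentation performance", "interobserver variability",
               "correction time", "delineation confidence", "total"),
    n_tests = c(2L * length(organs), 2L * length(organs), 1L, length(organs),
                m_tests),
    alpha_per_test = alpha_per_test)
  emit(mult, "multiplicity.csv")

  provenance <- list(config_hash = fnv1a_hash(unclass(config)),
                     seed = config$seed,
                     package_version = as.character(packageVersion("autosegeval")))
  report <- structure(list(
    descriptives = descr, model_fits = fits, icc = icc_tab,
    confidence = wf$confidence, time_comparison = wf$time,
    alpha_per_test = alpha_per_test, m_tests = m_tests,
    provenance = provenance, out_dir = out_dir), class = "study_report")
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  report
}

format_report <- function(x) {
  stopifnot(inherits(x, "study_report"))
  star <- function(sig) ifelse(!is.na(sig) & sig, " *", "")
  d <- x$descriptives
  lines <- c(
    "Autosegmentation evaluation report",
    "==================================",
    sprintf("provenance: config %s, seed %d, autosegeval %s",
            x$provenance$config_hash, x$provenance$seed,
            x$provenance$package_version),
    sprintf("multiplicity: %d tests, per-test alpha = %.4f (family-wise 0.05); * marks p < %.4f",
            x$m_tests, x$alpha_per_test, x$alpha_per_test),
    "",
    "Agreement metrics, mean [SD] per organ and arm:")
  for (i in seq_len(nrow(d)))
    lines <- c(lines, sprintf("  %-18s %-17s n=%3d  DSC %.2f [%.2f]  HD95 %5.2f [%5.2f] mm",
                              d$organ[i], d$imaging_system[i], d$n[i],
                              d$dsc_mean[i], d$dsc_sd[i], d$hd95_mean[i], d$hd95_sd[i]))
  f <- x$model_fits
  lines <- c(lines, "", "Imaging-system effect (high-performance minus conventional), crossed random-intercepts model:")
  for (i in seq_len(nrow(f)))
    lines <- c(lines, sprintf("  %-18s %-5s coef %8.4f (SE %.4f), df %6.1f, p = %s%s",
                              f$organ[i], f$metric[i], f$coefficient[i], f$se[i],
                              f$df[i], format.pval(f$p_value[i], digits = 2),
                              star(f$significant[i])))
  ic <- x$icc
  lines <- c(lines, "", "Interobserver ICC (observer variance / total variance; bootstrap mean in parentheses):")
  for (i in seq_len(nrow(ic)))
    lines <- c(lines, sprintf("  %-18s %-5s hp %.2f (%.2f)  conv %.2f (%.2f)  delta 95%% CI (%.2f, %.2f)  p = %s%s",
                              ic$organ[i], ic$metric[i], ic$icc_hp[i], ic$boot_mean_hp[i],
                              ic$icc_conv[i], ic$boot_mean_conv[i],
                              ic$delta_ci_lower[i], ic$delta_ci_upper[i],
                              format.pval(ic$p_value[i], digits = 2),
                              star(ic$significant[i])))
  tcmp <- x$time_comparison
  lines <- c(lines, "",
             sprintf("Correction time (per-patient 5-organ total, observer-averaged): %s [%s] vs %s [%s] min, paired t p = %s%s",
                     fmt_mmss(tcmp$mean_hp_s), fmt_mmss(tcmp$sd_hp_s),
                     fmt_mmss(tcmp$mean_conv_s), fmt_mmss(tcmp$sd_conv_s),
                     format.pval(tcmp$p_value, digits = 2), star(tcmp$significant)))
  cf <- x$confidence
  lines <- c(lines, "", "Delineation confidence (1 = very uncertain .. 5 = completely confident):")
  for (i in seq_len(nrow(cf)))
    lines <- c(lines, sprintf("  %-18s hp %.1f [%.1f]  conv %.1f [%.1f]  Wilcoxon p = %s%s",
                              cf$organ[i], cf$mean_hp[i], cf$sd_hp[i],
                              cf$mean_conv[i], cf$sd_conv[i],
                              format.pval(cf$p_value[i], digits = 2),
                              star(cf$significant[i])))
  lines
}

#' @export
print.study_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
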