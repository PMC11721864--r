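#' Variance-ratio intraclass correlation for one imaging-system arm
#'
#' Decomposes the metric values of one arm (one organ, one metric) by the
#' two-way crossed model without replication, `y_ij = mu + p_i + o_j + e_ij`
#' (patients x observers), and returns the interobserver ICC defined as the
#' observer variance over the total variance,
#' `ICC = s2_obs / (s2_sys + s2_pat + s2_obs)`, where the systematic
#' component `s2_sys` is the residual of the two-way decomposition. With this
#' definition an ICC near 0 means observers are highly consistent — note this
#' inverts the usual reliability reading of an ICC.
#'
#' Balanced complete tables use the closed-form ANOVA (expected mean squares)
#' estimators; unbalanced tables fall back to REML. Negative component
#' estimates are truncated at zero before the ratio.
#'
#' @param table `data.frame` for a single imaging system with columns
#'   `patient_id`, `observer_id` and the response; one observation per
#'   (patient, observer) cell.
#' @param response response column name.
#' @return object of class `icc_estimate`: list with `icc`,
#'   `sigma2_observer`, `sigma2_patient`, `sigma2_systematic`, `n_patients`,
#'   `n_observers`, `degenerate` (TRUE when total variance is 0, in which
#'   case `icc = 0`).
#' @export
icc_point <- function(table, response = "value") {
  stopifnot(is.data.frame(table))
  need <- c("patient_id", "observer_id", response)
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if ("imaging_system" %in% names(table) &&
      length(unique(table$imaging_system)) > 1L)
    stop("icc_point works on a single imaging-system arm; filter first")
  table <- table[is.finite(table[[response]]), , drop = FALSE]
  pat <- factor(table$patient_id); obs <- factor(table$observer_id)
  if (nlevels(pat) < 2L || nlevels(obs) < 2L)
    stop("need at least 2 patients and 2 observers")
  if (anyDuplicated(paste(pat, obs)))
    stop("more than one observation per (patient, observer) cell")
  y <- as.numeric(table[[response]])

  balanced <- length(y) == nlevels(pat) * nlevels(obs)
  if (balanced) {
    M <- matrix(NA_real_, nlevels(pat), nlevels(obs))
    M[cbind(as.integer(pat), as.integer(obs))] <- y
    comp <- icc_components_matrix(M)
  } else {
    f <- reml_crossed(y, NULL, as.character(pat), as.character(obs))
    comp <- c(patient = f$sigma2_patient, observer = f$sigma2_observer,
              residual = f$sigma2_residual)
  }
  total <- sum(comp)
  structure(list(
    icc = if (total > 0) unname(comp["observer"] / total) else 0,
    sigma2_observer = unname(comp["observer"]),
    sigma2_patient = unname(comp["patient"]),
    sigma2_systematic = unname(comp["residual"]),
    n_patients = nlevels(pat), n_observers = nlevels(obs),
    degenerate = total <= 0), class = "icc_estimate")
}

# closed-form two-way crossed ANOVA components from a patients x observers
# matrix; duplicated patient rows (bootstrap resamples) are fine.
icc_components_matrix <- function(M) {
  a <- nrow(M); b <- ncol(M)
  rm <- rowMeans(M); cm <- colMeans(M); g <- mean(M)
  msp <- b * sum((rm - g)^2) / (a - 1)
  mso <- a * sum((cm - g)^2) / (b - 1)
  mse <- sum((M - outer(rm, rep(1, b)) - outer(rep(1, a), cm) + g)^2) /
    ((a - 1) * (b - 1))
  c(patient = max((msp - mse) / b, 0),
    observer = max((mso - mse) / a, 0),
    residual = mse)
}

icc_from_matrix <- function(M) {
  comp <- icc_components_matrix(M)
  total <- sum(comp)
  if (total > 0) unname(comp["observer"] / total) else 0
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("<icc_estimate> ICC = %.4f (obs %.3g / total %.3g), %d patients x %d observers%s\n",
              x$icc, x$sigma2_observer,
              x$sigma2_observer + x$sigma2_patient + x$sigma2_systematic,
              x$n_patients, x$n_observers,
              if (x$degenerate) " [degenerate: zero total variance]" else ""))
  invisible(x)
}

#' Stratified patient-cluster bootstrap of the ICC
#'
#' Resamples patients with replacement within one imaging-system stratum,
#' carrying each sampled patient's complete set of observer readings
#' (observers are a fixed crossed factor and are never resampled), and
#' recomputes the variance-ratio ICC on every replicate. Replicates with zero
#' total variance contribute ICC = 0 and are counted, never dropped.
#'
#' @param table single-arm table as for [icc_point()].
#' @param B number of bootstrap replicates.
#' @param seed optional seed; fixed seed gives an identical replicate vector.
#' @param response response column name.
#' @return numeric vector of length `B` of replicate ICCs, with attribute
#'   `n_degenerate` (count of zero-total-variance replicates).
#' @export
stratified_bootstrap_icc <- function(table, B = 10000L, seed = NULL,
                                     response = "value") {
  stopifnot(is.data.frame(table), B >= 1L)
  table <- table[is.finite(table[[response]]), , drop = FALSE]
  pat <- factor(table$patient_id); obs <- factor(table$observer_id)
  a <- nlevels(pat); b <- nlevels(obs)
  balanced <- nrow(table) == a * b
  M <- NULL
  if (balanced) {
    M <- matrix(NA_real_, a, b)
    M[cbind(as.integer(pat), as.integer(obs))] <- as.numeric(table[[response]])
  }
  with_rng(seed, {
    out <- numeric(B); ndeg <- 0L
    for (r in seq_len(B)) {
      idx <- sample.int(a, a, replace = TRUE)
      if (balanced) {
        icc <- icc_from_matrix(M[idx, , drop = FALSE])
        if (icc == 0 && var(as.vector(M[idx, ])) <= 0) ndeg <- ndeg + 1L
        out[r] <- icc
      } else {
        keep <- unlist(lapply(seq_along(idx), function(z) which(as.integer(pat) == idx[z])))
        sub <- table[keep, , drop = FALSE]
        sub$patient_id <- rep(seq_along(idx),
                              times = tabulate(as.integer(pat))[idx])
        est <- icc_point(sub, response = response)
        if (est$degenerate) ndeg <- ndeg + 1L
        out[r] <- est$icc
      }
    }
    attr(out, "n_degenerate") <- ndeg
    out
  })
}

#' Compare bootstrap ICC distributions between the two imaging systems
#'
#' Applies the Welch two-sample t-test to the two bootstrap replicate vectors
#' and reports the 95% percentile interval of the paired-replicate difference
#' (conventional minus high-performance).
#'
#' @param boot_hp,boot_conv replicate vectors from
#'   [stratified_bootstrap_icc()] for the high-performance and conventional
#'   arms (equal length for the paired difference interval).
#' @param icc_hp,icc_conv optional point estimates to carry in the result.
#' @return object of class `icc_comparison`: `icc_hp`, `icc_conv`,
#'   `boot_mean_hp`, `boot_mean_conv`, `delta_ci` (2.5% and 97.5% percentiles
#'   of `boot_conv - boot_hp`), `welch_t`, `welch_df`, `p_value`, `B`,
#'   `degenerate`.
#' @export
compare_icc <- function(boot_hp, boot_conv, icc_hp = NULL, icc_conv = NULL) {
  stopifnot(is.numeric(boot_hp), is.numeric(boot_conv),
            length(boot_hp) >= 1L, length(boot_conv) >= 1L)
  if (length(boot_hp) != length(boot_conv))
    stop("replicate vectors must have equal length for the paired difference interval")
  delta <- boot_conv - boot_hp
  dci <- unname(quantile(delta, c(0.025, 0.975), type = 7, names = FALSE))
  degenerate <- (var(boot_hp) == 0 && var(boot_conv) == 0)
  if (degenerate) {
    wt <- list(statistic = 0, parameter = NA_real_,
               p.value = 1)
  } else {
    wt <- t.test(boot_conv, boot_hp, var.equal = FALSE)
  }
  structure(list(
    icc_hp = icc_hp, icc_conv = icc_conv,
    boot_mean_hp = mean(boot_hp), boot_mean_conv = mean(boot_conv),
    delta_ci = dci,
    welch_t = unname(wt$statistic), welch_df = unname(wt$parameter),
    p_value = unname(wt$p.value), B = length(boot_hp),
    degenerate = degenerate), class = "icc_comparison")
}

#' @export
print.icc_comparison <- function(x, ...) {
  cat(sprintf("<icc_comparison> bootstrap means %.3f (hp) vs %.3f (conv), delta 95%% CI (%.3f, %.3f), Welch p = %.3g%s\n",
              x$boot_mean_hp, x$boot_mean_conv, x$delta_ci[1], x$delta_ci[2],
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
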