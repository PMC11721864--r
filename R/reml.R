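#' Crossed random-intercepts model for two-arm agreement metrics
#'
#' Fits `y = beta0 + beta1 x + u_patient + v_observer + eps` by restricted
#' maximum likelihood, where `x` indicates the imaging-system arm and the
#' patient and observer intercepts are crossed (every observer reads every
#' patient). The profiled REML criterion is maximised by bounded quasi-Newton
#' iterations on the log variance ratios from several deterministic starting
#' points; variance components that go to the boundary are truncated at zero
#' and the model is refitted without them.
#'
#' @param table `data.frame` with columns `patient_id`, `observer_id`,
#'   `imaging_system` and the response column; typically the output of
#'   [metrics_for_cohort()] or [generate_metric_table()]. Rows with missing
#'   response are dropped.
#' @param response name of the response column (`"dsc"`, `"hd95"` or
#'   `"value"`).
#' @param organ optional organ to select when `table` has an `organ` column
#'   with several organs.
#' @param reference imaging-system label coded `x = 0`; with the default
#'   `"conventional"`, `beta1` is the high-performance minus conventional
#'   effect, so a positive Dice coefficient favours the high-performance arm.
#' @return object of class `crossed_model_fit` with elements `beta0`, `beta1`,
#'   `se_beta1`, `df`, `p_value`, `t_statistic`, `sigma2_patient`,
#'   `sigma2_observer`, `sigma2_residual`, `reml_loglik`, `converged`,
#'   `n_obs`, `arms`, `degenerate`.
#' @seealso [test_fixed_effect()] for the Satterthwaite-adjusted test alone.
#' @export
fit_crossed_model <- function(table, response = "dsc", organ = NULL,
                              reference = "conventional") {
  stopifnot(is.data.frame(table))
  need <- c("patient_id", "observer_id", "imaging_system", response)
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(organ)) {
    if (!"organ" %in% names(table)) stop("table has no `organ` column")
    table <- table[table$organ == organ, , drop = FALSE]
  } else if ("organ" %in% names(table) && length(unique(table$organ)) > 1L)
    stop("table contains several organs; pass `organ = `")
  table <- table[is.finite(table[[response]]), , drop = FALSE]
  sys <- unique(table$imaging_system)
  if (length(sys) != 2L) stop("both imaging systems must be present")
  if (!reference %in% sys)
    stop("`reference` must be one of: ", paste(sys, collapse = ", "))
  treated <- setdiff(sys, reference)
  if (length(unique(table$patient_id)) < 2L)
    stop("need at least 2 patients")
  if (length(unique(table$observer_id)) < 2L)
    stop("need at least 2 observers")

  y <- as.numeric(table[[response]])
  x <- as.numeric(table$imaging_system == treated)
  fit <- reml_crossed(y, x, table$patient_id, table$observer_id)
  fit$arms <- c(reference = reference, treated = treated)
  fit$response <- response
  if (!fit$degenerate) {
    tst <- test_fixed_effect(fit)
    fit$t_statistic <- tst$t_statistic
    fit$df <- tst$df
    fit$p_value <- tst$p_value
  }
  fit
}

# core REML engine; x may be NULL (intercept-only, used by the ICC fallback)
reml_crossed <- function(y, x, patient, observer) {
  n <- length(y)
  X <- if (is.null(x)) matrix(1, n, 1) else cbind(1, x)
  p <- ncol(X)
  A <- outer(patient, patient, "==") * 1
  B <- outer(observer, observer, "==") * 1
  In <- diag(n)

  base <- list(y = y, X = X, p = p, n = n, A = A, B = B, In = In)

  if (var(y) < 1e-25) {
    return(structure(list(
      beta0 = mean(y), beta1 = if (p == 2) 0 else NA_real_,
      se_beta1 = 0, t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      sigma2_patient = 0, sigma2_observer = 0, sigma2_residual = 0,
      reml_loglik = Inf, converged = TRUE, n_obs = n, degenerate = TRUE,
      internals = base), class = "crossed_model_fit"))
  }

  # profiled -2 REML log-likelihood at variance ratios (lam_p, lam_o)
  prof <- function(lam) {
    W <- In
    if (lam[1] > 0) W <- W + lam[1] * A
    if (lam[2] > 0) W <- W + lam[2] * B
    R <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(R)) return(list(dev = Inf))
    M <- backsolve(R, cbind(X, y), transpose = TRUE)
    MX <- M[, seq_len(p), drop = FALSE]; My <- M[, p + 1]
    XtWX <- crossprod(MX); XtWy <- crossprod(MX, My)
    bhat <- solve(XtWX, XtWy)
    rWr <- max(sum(My^2) - sum(bhat * XtWy), 1e-300)
    s2 <- rWr / (n - p)
    dev <- 2 * sum(log(diag(R))) + as.numeric(determinant(XtWX)$modulus) +
      (n - p) * (1 + log(2 * pi * s2))
    list(dev = dev, bhat = drop(bhat), s2 = s2, XtWX = XtWX)
  }

  # MoM starting values from the crossed ANOVA decomposition
  mom <- mom_components(y, x, patient, observer)
  s2e0 <- max(mom["residual"], 1e-8 * var(y))
  start_main <- log(pmax(c(mom["patient"], mom["observer"]), 1e-4 * s2e0) / s2e0)
  starts <- list(start_main, c(log(0.5), log(0.5)), c(log(4), log(0.02)))

  active <- c(TRUE, TRUE)
  lam_hat <- c(0, 0); best <- NULL; conv <- TRUE
  repeat {
    k <- sum(active)
    if (k == 0L) { best <- prof(c(0, 0)); lam_hat <- c(0, 0); break }
    objective <- function(theta) {
      lam <- c(0, 0); lam[active] <- exp(theta)
      prof(lam)$dev
    }
    best_opt <- NULL
    for (st in starts) {
      o <- tryCatch(
        stats::nlminb(st[active], objective,
                      lower = rep(-30, k), upper = rep(16, k),
                      control = list(rel.tol = 1e-14, iter.max = 500)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best_opt) || o$objective < best_opt$objective))
        best_opt <- o
    }
    if (is.null(best_opt)) { conv <- FALSE; best <- prof(c(0, 0)); break }
    lam_hat <- c(0, 0); lam_hat[active] <- exp(best_opt$par)
    at_zero <- active & (lam_hat < 1e-7)
    if (!any(at_zero)) {
      best <- prof(lam_hat)
      conv <- conv && best_opt$convergence %in% c(0, 1)
      break
    }
    active <- active & !at_zero  # truncate and refit without the component
  }

  s2e <- best$s2
  XtWXi <- solve(best$XtWX)
  fit <- list(
    beta0 = best$bhat[1],
    beta1 = if (p == 2) best$bhat[2] else NA_real_,
    se_beta1 = if (p == 2) sqrt(max(XtWXi[2, 2], 0) * s2e) else NA_real_,
    t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
    sigma2_patient = lam_hat[1] * s2e,
    sigma2_observer = lam_hat[2] * s2e,
    sigma2_residual = s2e,
    reml_loglik = -best$dev / 2,
    converged = conv, n_obs = n, degenerate = FALSE,
    internals = base)
  structure(fit, class = "crossed_model_fit")
}

# Closed-form expected-mean-squares (method-of-moments) estimators for the
# balanced crossed design; used as optimizer starting values. Works on
# unbalanced data too (as a rough start) via cell means.
mom_components <- function(y, x, patient, observer) {
  X <- if (is.null(x)) matrix(1, length(y), 1) else cbind(1, x)
  res <- stats::lm.fit(X, y)$residuals
  pat <- factor(patient); obs <- factor(observer)
  a <- nlevels(pat); b <- nlevels(obs); n <- length(y)
  pm <- tapply(res, pat, mean); om <- tapply(res, obs, mean)
  ssp <- sum((n / a) * pm^2); sso <- sum((n / b) * om^2)
  sse <- sum((res - pm[pat] + mean(res) - om[obs])^2)
  dfe <- max(n - a - b - ncol(X) + 2, 1)
  mse <- sse / dfe
  msp <- ssp / (a - 1); mso <- sso / (b - 1)
  c(patient = max((msp - mse) / (n / a), 0),
    observer = max((mso - mse) / (n / b), 0),
    residual = mse)
}

#' @export
print.crossed_model_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<crossed_model_fit> degenerate (zero total variance)\n")
    return(invisible(x))
  }
  cat(sprintf("<crossed_model_fit> n = %d, %s\n", x$n_obs,
              if (isTRUE(x$converged)) "converged" else "NOT CONVERGED"))
  cat(sprintf("  beta1 (%s - %s): %.5g (SE %.3g), t = %.3f, df = %.1f, p = %.4g\n",
              x$arms["treated"], x$arms["reference"], x$beta1, x$se_beta1,
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  variance components: patient %.4g, observer %.4g, residual %.4g\n",
              x$sigma2_patient, x$sigma2_observer, x$sigma2_residual))
  invisible(x)
}

# -2 REML log-likelihood as a function of the variance components themselves
# (natural scale), used for the Satterthwaite covariance of the components.
reml_dev_sigma <- function(fit, s2) {
  b <- fit$internals
  V <- s2[3] * b$In + s2[1] * b$A + s2[2] * b$B
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  M <- backsolve(R, cbind(b$X, b$y), transpose = TRUE)
  MX <- M[, seq_len(b$p), drop = FALSE]; My <- M[, b$p + 1]
  XtVX <- crossprod(MX)
  bhat <- solve(XtVX, crossprod(MX, My))
  rVr <- sum(My^2) - sum(bhat * crossprod(MX, My))
  2 * sum(log(diag(R))) + as.numeric(determinant(XtVX)$modulus) + rVr +
    (b$n - b$p) * log(2 * pi)
}

# sampling variance of the treated-arm coefficient at given components
var_beta1_sigma <- function(fit, s2) {
  b <- fit$internals
  V <- s2[3] * b$In + s2[1] * b$A + s2[2] * b$B
  R <- chol(V)
  MX <- backsolve(R, b$X, transpose = TRUE)
  XtVXi <- solve(crossprod(MX))
  XtVXi[b$p, b$p]
}

#' Satterthwaite-adjusted test of the imaging-system effect
#'
#' Computes `t = beta1 / se(beta1)` and refers it to a t distribution whose
#' denominator degrees of freedom follow Satterthwaite's approximation:
#' `df = 2 f^2 / (g' C g)` where `f = Var(beta1)` as a function of the
#' variance components, `g` its gradient, and `C` the asymptotic covariance
#' of the REML component estimates (inverse observed information). For
#' balanced complete data this reproduces the exact pooled-residual ANOVA
#' F test of the arm effect, which is also what the Kenward-Roger adjustment
#' gives there; for unbalanced data it is an approximation.
#'
#' @param fit a `crossed_model_fit` from [fit_crossed_model()].
#' @return list with `t_statistic`, `df`, `p_value`, `se_beta1`, and a
#'   `degenerate` flag (zero residual variance gives `p = 0` if `beta1 != 0`,
#'   else 1, with `df = NA`).
#' @export
test_fixed_effect <- function(fit) {
  stopifnot(inherits(fit, "crossed_model_fit"))
  if (!isTRUE(fit$converged))
    warning("testing a fit that did not converge")
  if (fit$degenerate || fit$sigma2_residual <= 0) {
    beta1 <- fit$beta1
    return(list(t_statistic = NA_real_, df = NA_real_,
                p_value = if (is.finite(beta1) && beta1 != 0) 0 else 1,
                se_beta1 = fit$se_beta1, degenerate = TRUE))
  }
  s2 <- c(fit$sigma2_patient, fit$sigma2_observer, fit$sigma2_residual)
  act <- which(s2 > 0)
  hg <- 1e-5 * s2  # gradient step, relative
  hh <- 1e-3 * s2  # Hessian step, relative (curvature needs a larger step)

  fval <- var_beta1_sigma(fit, s2)
  grad <- vapply(act, function(k) {
    e <- numeric(3); e[k] <- hg[k]
    (var_beta1_sigma(fit, s2 + e) - var_beta1_sigma(fit, s2 - e)) / (2 * hg[k])
  }, numeric(1))

  # observed information of -log REML likelihood in component coordinates
  half_dev <- function(sv) 0.5 * reml_dev_sigma(fit, sv)
  m <- length(act)
  H <- matrix(NA_real_, m, m)
  f0 <- half_dev(s2)
  for (i in seq_len(m)) {
    ei <- numeric(3); ei[act[i]] <- hh[act[i]]
    for (j in i:m) {
      ej <- numeric(3); ej[act[j]] <- hh[act[j]]
      if (i == j) {
        H[i, i] <- (half_dev(s2 + ei) - 2 * f0 + half_dev(s2 - ei)) /
          (hh[act[i]]^2)
      } else {
        H[i, j] <- H[j, i] <-
          (half_dev(s2 + ei + ej) - half_dev(s2 + ei - ej) -
             half_dev(s2 - ei + ej) + half_dev(s2 - ei - ej)) /
          (4 * hh[act[i]] * hh[act[j]])
      }
    }
  }
  C <- tryCatch(solve(H), error = function(e) NULL)
  denom <- if (!is.null(C)) drop(t(grad) %*% C %*% grad) else NA_real_
  df <- if (is.finite(denom) && denom > 0) 2 * fval^2 / denom
        else fit$n_obs - fit$internals$p  # conservative fallback
  se <- sqrt(fval)
  tstat <- fit$beta1 / se
  p <- 2 * pt(-abs(tstat), df)
  list(t_statistic = tstat, df = df, p_value = p, se_beta1 = se,
       degenerate = FALSE)
}
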