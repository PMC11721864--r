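# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity from first principles (enumeration,
# closed forms) rather than reusing package internals.

# --- geometry oracles -------------------------------------------------------

bf_dice <- function(a, b) {
  ia <- which(a$voxels); ib <- which(b$voxels)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

bf_boundary <- function(v) {
  d <- dim(v)
  idx <- which(v, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in nb) {
      if (q[1] < 1 || q[2] < 1 || q[3] < 1 ||
          q[1] > d[1] || q[2] > d[2] || q[3] > d[3] || !v[q[1], q[2], q[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

# all-pairs boundary distances, pooled percentile (linear interpolation)
bf_hd <- function(a, b, prob = 0.95) {
  pa <- which(bf_boundary(a$voxels), arr.ind = TRUE)
  pb <- which(bf_boundary(b$voxels), arr.ind = TRUE)
  ca <- sweep(pa - 1, 2, a$spacing_mm, `*`)
  cb <- sweep(pb - 1, 2, b$spacing_mm, `*`)
  D2 <- outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2 +
    outer(ca[, 3], cb[, 3], "-")^2
  D <- sqrt(D2)
  da <- apply(D, 1, min); db <- apply(D, 2, min)
  unname(quantile(c(da, db), prob, type = 7))
}

# random pair of blob masks (unions of ellipsoids) on a shared small grid
random_blob_pair <- function(max_dim = 32L) {
  d <- sample(10:max_dim, 3L, replace = TRUE)
  sp <- sample(c(1, 1.5, 2, 2.5), 3L, replace = TRUE)
  blob <- function() {
    v <- array(FALSE, d)
    ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
    X <- array(ax[[1]], d)
    Y <- array(rep(ax[[2]], each = d[1]), d)
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
    for (e in seq_len(sample(1:2, 1))) {
      ctr <- vapply(1:3, function(a) runif(1, 0.3, 0.7) * max(ax[[a]]), numeric(1))
      semi <- vapply(1:3, function(a) runif(1, 0.15, 0.3) * max(ax[[a]]) + 2 * sp[a],
                     numeric(1))
      v <- v | (((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
                  ((Z - ctr[3]) / semi[3])^2 <= 1)
    }
    if (!any(v)) v[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
    binary_mask(v, sp)
  }
  list(a = blob(), b = blob())
}

# --- statistics oracles -----------------------------------------------------

# expected-mean-squares (method-of-moments) estimators for the balanced
# crossed two-arm design, truncated at zero
mom_oracle <- function(d) {
  a <- length(unique(d$patient_id)); b <- length(unique(d$observer_id))
  n <- nrow(d)
  res <- stats::resid(stats::lm(value ~ x, data = d))
  pm <- tapply(res, d$patient_id, mean); om <- tapply(res, d$observer_id, mean)
  msp <- (n / a) * sum(pm^2) / (a - 1)
  mso <- (n / b) * sum(om^2) / (b - 1)
  mse <- sum((res - pm[d$patient_id] - om[d$observer_id])^2) / (n - a - b)
  c(patient = max((msp - mse) / (n / a), 0),
    observer = max((mso - mse) / (n / b), 0),
    residual = mse)
}

# textbook Welch two-sample t-test (x minus y)
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y); vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exact signed-rank two-sided p by full enumeration of the 2^n sign patterns
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# balanced single-arm table drawn from the two-way crossed components model
sim_arm_table <- function(a, b, s2p, s2o, s2e) {
  M <- outer(rnorm(a, 0, sqrt(s2p)), rep(1, b), "+") +
    outer(rep(1, a), rnorm(b, 0, sqrt(s2o)), "+") +
    matrix(rnorm(a * b, 0, sqrt(s2e)), a, b)
  data.frame(patient_id = rep(sprintf("p%04d", 1:a), b),
             observer_id = rep(sprintf("o%d", 1:b), each = a),
             value = as.vector(M))
}

# tiny hand-built delineation records for metric-table plumbing tests
tiny_record <- function(pid, obs, sys, organ, shift = 0L, missing = FALSE,
                        time_s = 60, conf = 4L) {
  v <- array(FALSE, c(8, 8, 8)); v[3:5, 3:5, 3:5] <- TRUE
  w <- array(FALSE, c(8, 8, 8)); w[(3:5) + shift, 3:5, 3:5] <- TRUE
  m1 <- binary_mask(v, 2); m2 <- binary_mask(w, 2)
  list(patient_id = pid, observer_id = obs, imaging_system = sys, organ = organ,
       truth_mask = if (missing) NULL else m1,
       ai_mask = if (missing) NULL else m2,
       corrected_mask = if (missing) NULL else m1,
       correction_time_s = if (missing) NA_real_ else time_s,
       confidence = if (missing) NA_integer_ else conf,
       missing = missing)
}

# --- memoized default study run (shared by the acceptance suite) ------------

.acc_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.acc_cache$metrics)) {
    cfg <- cohort_config()  # the default study conditions, seed included
    cohort <- generate_cohort(cfg)
    .acc_cache$cohort <- cohort
    .acc_cache$metrics <- suppressMessages(metrics_for_cohort(cohort))
  }
  list(cohort = .acc_cache$cohort, metrics = .acc_cache$metrics)
}
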