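#' Echo selection: discard the first echo and trailing low-SNR points
#'
#' The first echo of a CPMG multi-echo series is the only pure primary
#' echo; subsequent echoes also contain stimulated-echo signal, so the
#' first image never enters the decay fit. Data points at long TEs whose
#' SNR (SI / noise SD) falls below `snr_floor` are then discarded, scanning
#' from the last echo backwards: only the trailing contiguous low-SNR run
#' is removed, an isolated low point interior to the curve is kept.
#'
#' @param data Data frame with columns `te_ms` (strictly increasing,
#'   positive) and `si` (non-negative signal intensity).
#' @param noise_sd Per-acquisition noise SD; 0 (or `NA`) disables the SNR
#'   rule.
#' @param config A [fit_config()].
#' @return Tibble of the surviving points (possibly 0 rows).
#' @export
#' @examples
#' s <- tibble::tibble(te_ms = 12.9 * (1:8), si = 500 * exp(-12.9 * (1:8) / 50))
#' nrow(select_points(s, noise_sd = 10))  # 7: only the first echo goes
select_points <- function(data, noise_sd, config = fit_config()) {
  data <- as_series(data)
  te <- data$te_ms[-1]
  si <- data$si[-1]
  if (!is.na(noise_sd) && noise_sd > 0) {
    low <- si / noise_sd < config$snr_floor
    k <- length(si)
    while (k >= 1 && low[k]) k <- k - 1
    te <- te[seq_len(k)]
    si <- si[seq_len(k)]
  }
  tibble(te_ms = te, si = si)
}

as_series <- function(data) {
  if (!is.data.frame(data) || !all(c("te_ms", "si") %in% names(data)))
    abort("A series needs columns `te_ms` and `si`.")
  if (nrow(data) && (any(data$te_ms <= 0) || any(diff(data$te_ms) <= 0)))
    abort("`te_ms` must be strictly increasing and positive.")
  if (any(data$si < 0)) abort("`si` must be non-negative (magnitude data).")
  data
}

#' Robust log-linear initialization of the decay fit
#'
#' Fits `ln(SI) = a + s * TE` by iteratively reweighted least squares with
#' Tukey bisquare weights (tuning constant 4.685, scale = median absolute
#' residual / 0.6745, re-estimated each iteration), then maps the line back
#' to the decay parameters: `beta0 = exp(a)` and `t2_ms0 = -1/s` (only
#' meaningful for a decaying series, `s < 0`). Standard errors come from
#' the weighted normal equations and p-values are two-tailed on the
#' t-distribution with (n - 2) degrees of freedom, testing each linear
#' estimate against zero. Points with `si <= 0` are dropped before the
#' logarithm.
#'
#' The log-transform makes plain least squares noise-sensitive (the error
#' distribution becomes asymmetric), hence the redescending bisquare
#' weights.
#'
#' @param data A (typically already [select_points()]-reduced) series.
#' @param config A [fit_config()].
#' @return A list of class `"loglinear_fit"`: `ok`, `reason`, `beta0`,
#'   `t2_ms0`, `p_beta`, `p_t2`, `se_beta0`, `se_t2`, linear-scale
#'   coefficients and SEs, `weights`, `n`.
#' @export
robust_loglinear_fit <- function(data, config = fit_config()) {
  data <- as_series(data)
  pos <- data$si > 0
  x <- data$te_ms[pos]
  y <- log(data$si[pos])
  n <- length(x)
  fail <- function(reason) {
    structure(list(ok = FALSE, reason = reason, beta0 = NA_real_,
                   t2_ms0 = NA_real_, p_beta = 1, p_t2 = 1,
                   se_beta0 = NA_real_, se_t2 = NA_real_,
                   intercept = NA_real_, slope = NA_real_,
                   se_intercept = NA_real_, se_slope = NA_real_,
                   weights = NULL, n = n),
              class = "loglinear_fit")
  }
  if (n < 3) return(fail("too_few_points"))
  X <- cbind(1, x)
  w <- rep(1, n)
  for (it in seq_len(config$irls_maxit)) {
    fit <- stats::lm.wfit(X, y, w)
    r <- fit$residuals
    s <- median(abs(r)) / 0.6745
    if (s < 1e-10 * max(1, max(abs(y)))) {
      w_new <- rep(1, n)
    } else {
      u <- r / (config$irls_tuning * s)
      w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    }
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < config$irls_tol) break
  }
  if (sum(w > 0) < 3) return(fail("degenerate_weights"))
  fit <- stats::lm.wfit(X, y, w)
  a <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  r <- fit$residuals
  sigma2 <- sum(w * r^2) / (n - 2)
  xtx <- crossprod(X * sqrt(w))
  cov <- tryCatch(sigma2 * solve(xtx), error = function(e) NULL)
  if (is.null(cov)) return(fail("singular"))
  se <- sqrt(pmax(0, diag(cov)))
  tt <- abs(c(a, slope)) / se
  p <- 2 * pt(-tt, df = n - 2)
  p[!is.finite(p)] <- 0  # zero-residual exact fits
  beta0 <- exp(a)
  if (!(slope < -1e-10)) {  # flat within numerical noise counts as non-decaying
    out <- fail("non_decaying")
    out$beta0 <- beta0
    out$intercept <- a
    out$slope <- slope
    out$p_beta <- p[1]
    out$n <- n
    return(out)
  }
  structure(list(ok = TRUE, reason = NA_character_,
                 beta0 = beta0, t2_ms0 = -1 / slope,
                 p_beta = p[1], p_t2 = p[2],
                 se_beta0 = beta0 * se[1], se_t2 = se[2] / slope^2,
                 intercept = unname(a), slope = unname(slope),
                 se_intercept = se[1], se_slope = se[2],
                 weights = w, n = n),
            class = "loglinear_fit")
}

# Unconstrained-by-SNR smoothing fit used only for the synthetic PDW
# image: all post-first-echo points, default start. Returns c(beta, t2)
# or NULL.
curve_fit_all_points <- function(te_ms, si, config) {
  te <- te_ms[-1]
  siv <- si[-1]
  if (length(te) < config$min_points) return(NULL)
  lm <- tryCatch(
    minpack.lm::nls.lm(
      par = c(config$default_init[["beta"]], config$default_init[["t2_ms"]]),
      fn = function(p) siv - p[1] * exp(-te / p[2]),
      lower = c(1e-12, config$t2_bounds_ms[1]),
      upper = c(Inf, config$t2_bounds_ms[2]),
      control = minpack.lm::nls.lm.control(
        ftol = config$lm_tol, ptol = config$lm_tol, gtol = 0,
        maxiter = config$lm_maxit)),
    error = function(e) NULL)
  if (is.null(lm) || !(lm$info %in% 1:4)) return(NULL)
  lm$par
}

# Core voxel engine shared by fit_monoexponential() and fit_t2_map().
# Returns a plain named list (kept lightweight: it runs once per voxel).
fit_voxel <- function(te_ms, si, noise_sd, config) {
  m <- length(te_ms)
  reject <- function(reason, n_used = 0L, init = NA_character_) {
    cb <- curve_fit_all_points(te_ms, si, config)
    list(beta = NA_real_, t2_ms = NA_real_, se_beta = NA_real_,
         se_t2 = NA_real_, p_beta = 1, p_t2 = 1,
         ci95_beta_lo = NA_real_, ci95_beta_hi = NA_real_,
         ci95_t2_lo = NA_real_, ci95_t2_hi = NA_real_,
         n_points_used = as.integer(n_used), init_source = init,
         accepted = FALSE, reject_reason = reason,
         rss = NA_real_, converged = FALSE,
         curve_beta = if (is.null(cb)) NA_real_ else cb[1],
         curve_t2_ms = if (is.null(cb)) NA_real_ else cb[2])
  }
  sel <- select_points(tibble(te_ms = te_ms, si = si), noise_sd, config)
  n <- nrow(sel)
  if (n < config$min_points) {
    reason <- if (m - 1L >= config$min_points) "below_noise" else "insufficient_points"
    return(reject(reason, n))
  }
  rob <- robust_loglinear_fit(sel, config)
  use_rob <- rob$ok && rob$p_beta < config$alpha && rob$p_t2 < config$alpha &&
    rob$t2_ms0 > config$t2_bounds_ms[1] && rob$t2_ms0 <= config$t2_bounds_ms[2]
  if (use_rob) {
    start <- c(rob$beta0, rob$t2_ms0)
    init_source <- "robust_linear"
  } else {
    start <- c(config$default_init[["beta"]], config$default_init[["t2_ms"]])
    init_source <- "default"
  }
  te <- sel$te_ms
  siv <- sel$si
  res_fn <- function(p) siv - p[1] * exp(-te / p[2])
  jac_fn <- function(p) {
    e <- exp(-te / p[2])
    cbind(-e, -p[1] * te * e / p[2]^2)
  }
  lm <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = res_fn, jac = jac_fn,
      lower = c(1e-12, config$t2_bounds_ms[1]),
      upper = c(Inf, config$t2_bounds_ms[2]),
      control = minpack.lm::nls.lm.control(
        ftol = config$lm_tol, ptol = config$lm_tol, gtol = 0,
        maxiter = config$lm_maxit)),
    error = function(e) NULL)
  if (is.null(lm) || !(lm$info %in% 1:4)) {
    out <- reject("nonconverged", n, init_source)
    return(out)
  }
  beta <- lm$par[1]
  t2 <- lm$par[2]
  rss <- sum(lm$fvec^2)
  dof <- n - 2L
  sigma2 <- rss / dof
  J <- jac_fn(lm$par)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov))) {
    se <- c(Inf, Inf)
    p <- c(1, 1)
  } else {
    se <- sqrt(pmax(0, diag(cov)))
    tt <- abs(c(beta, t2)) / se
    p <- 2 * pt(-tt, df = dof)
    p[!is.finite(p)] <- 0  # exact (zero-residual) fits
  }
  tq <- qt(0.975, df = dof)
  accepted <- p[1] < config$alpha && p[2] < config$alpha
  list(beta = beta, t2_ms = t2, se_beta = se[1], se_t2 = se[2],
       p_beta = p[1], p_t2 = p[2],
       ci95_beta_lo = beta - tq * se[1], ci95_beta_hi = beta + tq * se[1],
       ci95_t2_lo = t2 - tq * se[2], ci95_t2_hi = t2 + tq * se[2],
       n_points_used = as.integer(n), init_source = init_source,
       accepted = accepted,
       reject_reason = if (accepted) NA_character_ else "nonsignificant",
       rss = rss, converged = TRUE,
       curve_beta = beta, curve_t2_ms = t2)
}

#' Voxelwise mono-exponential T2 fit with significance gating
#'
#' Fits `SI = beta * exp(-TE / T2)` to one voxel's echo series. The first
#' echo and any trailing SNR < 2 echoes are removed by [select_points()];
#' if fewer than `min_points` echoes survive the voxel is rejected. The
#' nonlinear Levenberg-Marquardt fit is initialized from the robust
#' log-linear fit when both of its estimates are significant
#' (p < `alpha`), otherwise from the defaults (beta = 500, T2 = 50 ms).
#' Standard errors come from the Gauss-Newton covariance
#' (residual variance x (J'J)^-1), p-values are two-tailed on the
#' t-distribution with (n_points_used - 2) degrees of freedom, 95%
#' confidence intervals are estimate +/- t_{0.975} * SE, and the voxel is
#' accepted only when both beta and T2 reject the null (p < `alpha`).
#'
#' @inheritParams select_points
#' @return An object of class `"t2_fit"`; see [tidy.t2_fit()] and
#'   [glance.t2_fit()].
#' @export
#' @examples
#' te <- 12.9 * (1:8)
#' fit <- fit_monoexponential(
#'   tibble::tibble(te_ms = te, si = 500 * exp(-te / 50)), noise_sd = 0)
#' glance(fit)$accepted
fit_monoexponential <- function(data, noise_sd, config = fit_config()) {
  data <- as_series(data)
  if (is.na(noise_sd) || noise_sd < 0)
    abort("`noise_sd` must be a non-negative number.")
  out <- fit_voxel(data$te_ms, data$si, noise_sd, config)
  structure(c(out, list(data = as_tibble(data), noise_sd = noise_sd,
                        config = config)),
            class = "t2_fit")
}

#' @export
print.t2_fit <- function(x, ...) {
  cat("Mono-exponential T2 fit\n")
  if (is.finite(x$t2_ms)) {
    cat(sprintf("  T2   = %.2f ms (SE %.3g, p = %.3g)\n", x$t2_ms, x$se_t2, x$p_t2))
    cat(sprintf("  beta = %.2f    (SE %.3g, p = %.3g)\n", x$beta, x$se_beta, x$p_beta))
  }
  cat(sprintf("  points used: %d; init: %s; accepted: %s%s\n",
              x$n_points_used, x$init_source %||% "-", x$accepted,
              if (!x$accepted) paste0(" (", x$reject_reason, ")") else ""))
  invisible(x)
}

#' Predicted decay curve of a fitted voxel
#'
#' @param object A `"t2_fit"`.
#' @param te_ms Echo times at which to evaluate `beta * exp(-TE/T2)`.
#' @param ... Unused.
#' @return Numeric vector of intensities.
#' @export
predict.t2_fit <- function(object, te_ms = object$data$te_ms, ...) {
  if (!is.finite(object$t2_ms)) return(rep(NA_real_, length(te_ms)))
  object$beta * exp(-te_ms / object$t2_ms)
}

#' Transverse-magnetization half-life
#'
#' The time for transverse magnetization to halve is `T2 * ln(2)`; it is
#' the natural unit for judging a TE grid (an 8-echo series ending at
#' about 3 half-lives samples the decay well). For the normal carotid wall
#' (T2 ~ 50 ms) the half-life is ~ 35 ms.
#'
#' @param t2_ms Positive T2 value(s) in ms.
#' @return `t2_ms * log(2)`, in ms.
#' @export
#' @examples
#' round(halflife_ms(50))  # 35
halflife_ms <- function(t2_ms) {
  if (any(t2_ms <= 0)) abort("`t2_ms` must be positive.")
  t2_ms * log(2)
}

#' Pixel size of a reconstructed image
#'
#' @param fov_mm Field of view (mm) along one dimension.
#' @param n_pixels Reconstructed (possibly zero-padded) matrix size along
#'   that dimension.
#' @return Pixel size in mm.
#' @export
#' @examples
#' pixel_size_mm(160, 640)  # 0.25
pixel_size_mm <- function(fov_mm, n_pixels) {
  if (fov_mm <= 0 || n_pixels <= 0) abort("Arguments must be positive.")
  fov_mm / n_pixels
}

#' Estimate the acquisition noise SD from a background region
#'
#' On magnitude images, a signal-free background pixel follows a Rayleigh
#' distribution with mean `noise_sd * sqrt(pi/2)` and SD
#' `noise_sd * sqrt(2 - pi/2)`. The estimator inverts one of these moments
#' on the last echo of the series (the echo least likely to retain tissue
#' signal).
#'
#' @param series A `"multiecho_stack"` (or list with `stack`).
#' @param background_mask Logical matrix marking signal-free pixels.
#' @param method `"mean"` (default) or `"sd"` moment inversion.
#' @return Estimated per-channel noise SD (0, with a warning, for an
#'   all-zero background).
#' @export
estimate_noise_sd <- function(series, background_mask,
                              method = c("mean", "sd")) {
  method <- match.arg(method)
  stack <- series$stack
  if (!any(background_mask)) abort("`background_mask` is empty.")
  v <- array(stack[, , dim(stack)[3]], dim(stack)[1:2])[background_mask]
  if (all(v == 0)) {
    warn("Background is identically zero; returning noise_sd = 0.")
    return(0)
  }
  switch(method,
         mean = mean(v) / sqrt(pi / 2),
         sd = sd(v) / sqrt(2 - pi / 2))
}
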