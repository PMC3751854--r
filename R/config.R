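#' Fitting and classification options
#'
#' Collects the tunable parameters of the voxelwise T2 fit and of the
#' synthetic proton-density-weighted (PDW) image used for calcification
#' detection. Defaults follow the published analysis where it states them
#' (significance level 0.05, default initial values beta = 500 and
#' T2 = 50 ms, SNR floor 2, PDW query TE 14 ms) and standard numerical
#' practice elsewhere.
#'
#' @param min_points Minimum surviving echoes for a two-parameter fit
#'   (default 3, so the t-test keeps at least one residual degree of
#'   freedom).
#' @param alpha Two-tailed significance level for the beta and T2 gates.
#' @param snr_floor Echoes at long TE whose SI/noise_sd falls below this
#'   value are discarded (trailing run only; interior dips are kept).
#' @param default_init Named vector `c(beta =, t2_ms =)` used when the
#'   robust log-linear initializer is not significant.
#' @param t2_bounds_ms Box constraints on T2 for the nonlinear fit (ms).
#' @param lm_tol,lm_maxit Levenberg-Marquardt relative tolerance and
#'   iteration cap.
#' @param irls_tuning Tukey bisquare tuning constant (4.685 gives 95%
#'   efficiency at the Gaussian model).
#' @param irls_maxit,irls_tol IRLS iteration cap and weight-change
#'   convergence tolerance.
#' @param pdw_te_ms TE (ms) at which the synthetic PDW image is evaluated.
#' @param pdw_mode `"fitted"` evaluates the fitted decay curve whenever the
#'   nonlinear fit converged (even if not significant), falling back to the
#'   measured first-echo intensity when no estimates exist; `"first_echo"`
#'   uses the fitted curve only for accepted voxels and the measured first
#'   echo for all others.
#'
#' @return A list of class `"fit_config"`.
#' @export
#' @examples
#' fit_config(alpha = 0.01)
fit_config <- function(min_points = 3L,
                       alpha = 0.05,
                       snr_floor = 2,
                       default_init = c(beta = 500, t2_ms = 50),
                       t2_bounds_ms = c(1, 2000),
                       lm_tol = 1e-8,
                       lm_maxit = 200L,
                       irls_tuning = 4.685,
                       irls_maxit = 50L,
                       irls_tol = 1e-8,
                       pdw_te_ms = 14,
                       pdw_mode = c("fitted", "first_echo")) {
  pdw_mode <- match.arg(pdw_mode)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  if (pdw_te_ms <= 0) abort("`pdw_te_ms` must be positive.")
  if (min_points < 3) abort("`min_points` must be at least 3.")
  if (length(t2_bounds_ms) != 2 || diff(t2_bounds_ms) <= 0 || t2_bounds_ms[1] <= 0)
    abort("`t2_bounds_ms` must be an increasing positive pair.")
  structure(
    list(min_points = as.integer(min_points), alpha = alpha,
         snr_floor = snr_floor,
         default_init = c(beta = unname(default_init["beta"]),
                          t2_ms = unname(default_init["t2_ms"])),
         t2_bounds_ms = as.numeric(t2_bounds_ms),
         lm_tol = lm_tol, lm_maxit = as.integer(lm_maxit),
         irls_tuning = irls_tuning, irls_maxit = as.integer(irls_maxit),
         irls_tol = irls_tol,
         pdw_te_ms = pdw_te_ms, pdw_mode = pdw_mode),
    class = "fit_config")
}

#' Read or write a run configuration as JSON
#'
#' A run configuration is a plain named list (fitting options, classifier
#' priors, paths, seed, ...) serialized to JSON. `fit_config` entries
#' survive the round trip.
#'
#' @param config A named list (may contain a `fit` entry from [fit_config()]).
#' @param path File path for the JSON document.
#' @return `read_run_config()` returns the named list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  config <- lapply(config, function(x)
    if (inherits(x, "fit_config")) unclass(x) else x)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$fit)) cfg$fit <- do.call(fit_config, cfg$fit[names(cfg$fit) %in% names(formals(fit_config))])
  cfg
}
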