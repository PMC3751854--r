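#' Fit a quantitative T2 map over a region of interest
#'
#' Applies the gated mono-exponential fit ([fit_monoexponential()]) to every
#' voxel of the ROI and assembles the accepted T2 values into a map,
#' recording a rejection reason (`insufficient_points`, `below_noise`,
#' `nonsignificant`, `nonconverged`) for every voxel that does not pass.
#'
#' @param series A `"multiecho_stack"` (from [simulate_series()] or
#'   [read_series()]), or a list with `stack` (rows x cols x echoes) and
#'   `te_ms`.
#' @param roi_mask Logical matrix on the image grid selecting the voxels to
#'   fit (e.g. vessel wall plus muscle).
#' @param noise_sd Per-acquisition noise SD; if `NULL`, estimated with
#'   [estimate_noise_sd()] from `background_mask`.
#' @param config A [fit_config()].
#' @param background_mask Optional logical matrix of signal-free pixels,
#'   used only when `noise_sd` is `NULL`.
#' @return An object of class `"t2_map"`: matrices `t2_ms` (NA where
#'   rejected), `accept_mask`, `reject_reason`, a per-voxel `fits` tibble
#'   (see [tidy.t2_map()]), the first-echo image (kept for the synthetic
#'   PDW fallback), `te_ms`, `noise_sd` and `config`.
#' @export
fit_t2_map <- function(series, roi_mask, noise_sd = NULL,
                       config = fit_config(), background_mask = NULL) {
  stack <- series$stack
  te <- series$te_ms
  dims <- dim(stack)
  if (length(dims) != 3 || dims[3] != length(te))
    abort("`series` must hold a rows x cols x echoes stack matching `te_ms`.")
  if (!is.logical(roi_mask)) roi_mask <- roi_mask > 0
  if (!all(dim(roi_mask) == dims[1:2]))
    abort("`roi_mask` is not on the image grid.")
  if (!any(roi_mask)) abort("`roi_mask` selects no voxels.")
  if (is.null(noise_sd)) {
    if (is.null(background_mask))
      abort("Supply `noise_sd` or a `background_mask` to estimate it from.")
    noise_sd <- estimate_noise_sd(series, background_mask)
  }

  idx <- which(roi_mask, arr.ind = TRUE)
  nv <- nrow(idx)
  rows <- vector("list", nv)
  for (i in seq_len(nv)) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rows[[i]] <- fit_voxel(te, stack[r, c, ], noise_sd, config)
  }
  fits <- dplyr::bind_rows(lapply(rows, as_tibble))
  fits <- dplyr::bind_cols(tibble(row = idx[, 1], col = idx[, 2]), fits)

  t2 <- matrix(NA_real_, dims[1], dims[2])
  acc <- matrix(FALSE, dims[1], dims[2])
  reason <- matrix(NA_character_, dims[1], dims[2])
  est_beta <- matrix(NA_real_, dims[1], dims[2])
  est_t2 <- matrix(NA_real_, dims[1], dims[2])
  lin <- (idx[, 2] - 1) * dims[1] + idx[, 1]
  acc[lin] <- fits$accepted
  t2[lin[fits$accepted]] <- fits$t2_ms[fits$accepted]
  reason[lin] <- fits$reject_reason
  est_beta[lin] <- fits$beta
  est_t2[lin] <- fits$t2_ms
  structure(list(t2_ms = t2, accept_mask = acc, reject_reason = reason,
                 fits = fits, roi_mask = roi_mask,
                 est_beta = est_beta, est_t2 = est_t2,
                 first_echo = array(stack[, , 1], dims[1:2]), te_ms = te,
                 noise_sd = noise_sd, config = config),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("T2 map: %d ROI voxels, %d accepted (%.1f%%), noise SD %.3g\n",
              g$n_roi, g$n_accepted, 100 * g$n_accepted / g$n_roi, x$noise_sd))
  if (g$n_accepted)
    cat(sprintf("  accepted T2: median %.1f ms (IQR %.1f-%.1f)\n",
                median(x$t2_ms[x$accept_mask]),
                stats::quantile(x$t2_ms[x$accept_mask], 0.25),
                stats::quantile(x$t2_ms[x$accept_mask], 0.75)))
  invisible(x)
}

#' Synthetic image at an arbitrary echo time
#'
#' Evaluates each voxel's fitted decay curve `beta * exp(-te_query/T2)` at
#' a query TE and divides by the noise SD to obtain an SNR image. At a
#' short TE (default 14 ms) this is a synthetic proton-density-weighted
#' (PDW) image, the input of the calcification rule (SNR < 2).
#'
#' Two modes are available (see [fit_config()]). `"fitted"` (default)
#' evaluates a decay curve for every voxel: the gated fit's estimates
#' where the fit ran, otherwise a smoothing fit of all post-first-echo
#' points with no SNR trimming (for a near-signal-free voxel this yields a
#' smoothed noise-floor value rather than a single Rayleigh draw).
#' `"first_echo"` trusts only accepted fits and uses the measured
#' first-echo intensity for every other voxel.
#'
#' @param t2_map A [fit_t2_map()] result.
#' @param te_query_ms Query echo time in ms (> 0).
#' @param noise_sd SNR denominator; defaults to the map's noise SD.
#' @param mode Overrides `t2_map$config$pdw_mode` when given.
#' @return List with matrices `intensity` and `snr` (NA outside the ROI).
#' @export
#' @examples
#' # an accepted voxel with beta = 500, T2 = 50 evaluates to
#' 500 * exp(-14 / 50)  # 377.9 at TE = 14 ms
synthetic_image <- function(t2_map, te_query_ms = t2_map$config$pdw_te_ms,
                            noise_sd = t2_map$noise_sd, mode = NULL) {
  if (te_query_ms <= 0) abort("`te_query_ms` must be positive.")
  mode <- mode %||% t2_map$config$pdw_mode
  fits <- t2_map$fits
  dims <- dim(t2_map$t2_ms)
  intensity <- matrix(NA_real_, dims[1], dims[2])
  lin <- (fits$col - 1) * dims[1] + fits$row
  intensity[lin] <- t2_map$first_echo[lin]
  if (mode == "fitted") {
    u <- which(is.finite(fits$curve_t2_ms))
    intensity[lin[u]] <- fits$curve_beta[u] *
      exp(-te_query_ms / fits$curve_t2_ms[u])
  } else {
    u <- which(fits$accepted)
    intensity[lin[u]] <- fits$beta[u] * exp(-te_query_ms / fits$t2_ms[u])
  }
  if (noise_sd > 0) {
    snr <- intensity / noise_sd
  } else {
    snr <- intensity  # noise-free: SNR is infinite wherever signal exists
    snr[which(intensity > 0)] <- Inf
  }
  list(intensity = intensity, snr = snr)
}
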