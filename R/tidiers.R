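#' Tidy a voxel fit
#'
#' One row per model term (`beta`, `t2_ms`) with estimate, SE, t-statistic,
#' p-value and 95% confidence bounds, in the broom column convention.
#'
#' @param x A `"t2_fit"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy t2_fit
#' @export
tidy.t2_fit <- function(x, ...) {
  tibble(term = c("beta", "t2_ms"),
         estimate = c(x$beta, x$t2_ms),
         std.error = c(x$se_beta, x$se_t2),
         statistic = c(x$beta / x$se_beta, x$t2_ms / x$se_t2),
         p.value = c(x$p_beta, x$p_t2),
         conf.low = c(x$ci95_beta_lo, x$ci95_t2_lo),
         conf.high = c(x$ci95_beta_hi, x$ci95_t2_hi))
}

#' Glance at a voxel fit
#'
#' @param x A `"t2_fit"`.
#' @param ... Unused.
#' @return One-row tibble: `accepted`, `reject_reason`, `n_points_used`,
#'   `init_source`, `rss`, `df.residual`, `converged`.
#' @method glance t2_fit
#' @export
glance.t2_fit <- function(x, ...) {
  tibble(accepted = x$accepted, reject_reason = x$reject_reason,
         n_points_used = x$n_points_used, init_source = x$init_source,
         rss = x$rss, df.residual = max(0L, x$n_points_used - 2L),
         converged = x$converged)
}

#' Tidy a T2 map
#'
#' The flat per-voxel results table: one row per ROI voxel with estimates,
#' SEs, p-values, confidence bounds, points used, initialization source,
#' acceptance flag and rejection reason.
#'
#' @param x A `"t2_map"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy t2_map
#' @export
tidy.t2_map <- function(x, ...) x$fits

#' Glance at a T2 map
#'
#' @param x A `"t2_map"`.
#' @param ... Unused.
#' @return One-row tibble with ROI size, acceptance counts and the share
#'   of each rejection reason.
#' @method glance t2_map
#' @export
glance.t2_map <- function(x, ...) {
  f <- x$fits
  tibble(n_roi = nrow(f),
         n_accepted = sum(f$accepted),
         n_rejected = sum(!f$accepted),
         frac_rejected = mean(!f$accepted),
         n_nonsignificant = sum(f$reject_reason %in% "nonsignificant"),
         n_below_noise = sum(f$reject_reason %in% "below_noise"),
         n_insufficient = sum(f$reject_reason %in% "insufficient_points"),
         n_nonconverged = sum(f$reject_reason %in% "nonconverged"),
         noise_sd = x$noise_sd)
}

#' Tidy a class model
#'
#' @param x A `"class_model"`.
#' @param ... Unused.
#' @return Per-class tibble: `class`, `mu_ms`, `sd_ms`, `prior`, `n_train`.
#' @method tidy class_model
#' @export
tidy.class_model <- function(x, ...) x$params

#' Tidy a plaque segmentation
#'
#' @param x A `"plaque_segmentation"`.
#' @param ... Unused.
#' @return The per-class voxel-count tibble.
#' @method tidy plaque_segmentation
#' @export
tidy.plaque_segmentation <- function(x, ...) x$counts

#' Glance at a plaque segmentation
#'
#' @param x A `"plaque_segmentation"`.
#' @param ... Unused.
#' @return One-row tibble with wall size and per-outcome voxel counts.
#' @method glance plaque_segmentation
#' @export
glance.plaque_segmentation <- function(x, ...) {
  lab <- x$label_map[x$wall_mask]
  tibble(n_wall = length(lab),
         n_classified = sum(lab %in% x$model$classes),
         n_calcification = sum(lab == "calcification"),
         n_rejected = sum(lab == "rejected"))
}
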