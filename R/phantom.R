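#' Specify a digital carotid phantom
#'
#' Describes a 2D cross-section of a carotid artery as imaged by a
#' black-blood multi-echo spin-echo (CPMG) acquisition: a dark lumen
#' (ideal double-inversion-recovery suppression), an annular vessel wall,
#' circular plaque-component blobs embedded in the wall, an optional
#' sternocleidomastoid-muscle disc, and a noise level. Signal tissues carry
#' Gaussian distributions of T2 (ms) and of the mono-exponential amplitude
#' beta; calcification has beta ~ 0 and is effectively signal-free.
#'
#' The defaults emulate an advanced (type VI-like) plaque: a thick wall of
#' fibrous tissue (T2 56 +/- 9 ms) containing two lipid-rich necrotic core
#' blobs (37 +/- 5 ms), one large recent-intraplaque-haemorrhage blob
#' (107 +/- 25 ms) and a small calcification, with component proportions
#' close to those reported for segmented advanced carotid plaques
#' (roughly two thirds fibrous, one fifth LRNC, a few percent each of
#' recent IPH and calcification). The TE grid is 12.9 * (1..8) ms and the
#' default noise SD puts the measured first-echo SNR of the fibrous wall
#' near 30 and the last-echo SNR near 7, within the range typical of
#' carotid Multi-SE at 3 T.
#'
#' All coordinates are 1-based (row, col) with pixel centers at integer
#' positions; geometry is rasterized by pixel-center inclusion.
#'
#' @param grid_shape Integer pair (rows, cols).
#' @param pixel_size_mm Pixel size in mm (default 0.25, i.e. a 160 mm FOV
#'   reconstructed to 640 pixels).
#' @param lumen_center Numeric pair (row, col); defaults to the grid center.
#' @param lumen_radius_px,wall_thickness_px Vessel geometry in pixels.
#' @param wall_tissue Tissue label filling the annulus: `"fibrous"`
#'   (diseased wall, default) or `"wall"` (normal intima/media,
#'   54 +/- 13 ms).
#' @param component_blobs List of blobs, each
#'   `list(tissue = <label>, center = c(row, col), radius_px = <r>)`.
#'   Every blob must lie inside the wall annulus; overlaps resolve
#'   last-listed-wins. `NULL` keeps the defaults described above; use
#'   `list()` for a clean annulus.
#' @param muscle_blob Optional `list(center =, radius_px =)` disc of muscle
#'   outside the vessel, or `NULL` for none.
#' @param tissue_params Named list mapping tissue label to
#'   `c(t2_mean, t2_sd, beta_mean, beta_sd)`; see
#'   [default_tissue_params()].
#' @param te_grid_ms Strictly increasing positive echo times (ms).
#' @param noise_sd Per-channel Gaussian noise SD of the complex signal
#'   (Rician noise on magnitude images); 0 for noise-free.
#' @param first_echo_scale Multiplier in (0, 1] applied to the first echo
#'   only, emulating the primary-vs-stimulated-echo amplitude mismatch
#'   (the first echo is the only pure primary echo).
#' @param coil_profile Optional smooth multiplicative shading,
#'   `list(center = c(row, col), amplitude =, width_px =)`:
#'   the field is `1 + amplitude * exp(-d^2 / (2 width^2))`.
#' @param flow_artifact_amp Residual slow-flow lumen signal added to the
#'   first echo only (default 0; such artefacts do not affect T2 because
#'   the first echo is never fitted).
#' @param t2_floor_ms Lower truncation for sampled T2 values (default 1 ms).
#' @param seed Integer seed; geometry and tissue draws are reproducible
#'   given the seed.
#'
#' @return A validated list of class `"phantom_spec"`.
#' @seealso [build_phantom()], [simulate_series()]
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 48), lumen_radius_px = 5,
#'                      wall_thickness_px = 7, component_blobs = list(),
#'                      muscle_blob = NULL)
#' ph <- build_phantom(spec)
#' table(ph$label_map)
phantom_spec <- function(grid_shape = c(96L, 96L),
                         pixel_size_mm = 0.25,
                         lumen_center = NULL,
                         lumen_radius_px = 8,
                         wall_thickness_px = 16,
                         wall_tissue = "fibrous",
                         component_blobs = NULL,
                         muscle_blob = list(center = c(14, 14), radius_px = 8),
                         tissue_params = default_tissue_params(),
                         te_grid_ms = 12.9 * (1:8),
                         noise_sd = 11.25,
                         first_echo_scale = 0.85,
                         coil_profile = NULL,
                         flow_artifact_amp = 0,
                         t2_floor_ms = 1,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lumen_center)) lumen_center <- (grid_shape + 1) / 2
  outer <- lumen_radius_px + wall_thickness_px
  if (is.null(component_blobs)) {
    mid <- lumen_radius_px + wall_thickness_px / 2
    polar <- function(d, deg) lumen_center +
      d * c(-sin(deg * pi / 180), cos(deg * pi / 180))
    component_blobs <- list(
      list(tissue = "LRNC", center = polar(mid, 30), radius_px = 7),
      list(tissue = "LRNC", center = polar(mid, 150), radius_px = 7),
      list(tissue = "recent_IPH", center = polar(mid, 270), radius_px = 7),
      list(tissue = "calcification", center = polar(mid - 4, 210), radius_px = 3))
  }
  spec <- structure(
    list(grid_shape = grid_shape, pixel_size_mm = pixel_size_mm,
         lumen_center = as.numeric(lumen_center),
         lumen_radius_px = lumen_radius_px,
         wall_thickness_px = wall_thickness_px,
         wall_tissue = wall_tissue,
         component_blobs = component_blobs,
         muscle_blob = muscle_blob,
         tissue_params = tissue_params,
         te_grid_ms = as.numeric(te_grid_ms),
         noise_sd = noise_sd,
         first_echo_scale = first_echo_scale,
         coil_profile = coil_profile,
         flow_artifact_amp = flow_artifact_amp,
         t2_floor_ms = t2_floor_ms,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default tissue parameters of the carotid phantom
#'
#' Per-tissue `c(t2_mean, t2_sd, beta_mean, beta_sd)`. T2 distributions are
#' the in-vivo 3 T values for carotid tissue classes (LRNC 37 +/- 5 ms,
#' fibrous tissue 56 +/- 9 ms, normal intima/media 54 +/- 13 ms, recent IPH
#' 107 +/- 25 ms, sternocleidomastoid muscle 39 +/- 6 ms); calcification is
#' signal-free (beta ~ 0). Amplitudes are free parameters of the phantom;
#' the default mean 500 matches the conventional default initializer of the
#' nonlinear fit.
#'
#' @return Named list of numeric 4-vectors.
#' @export
default_tissue_params <- function() {
  list(
    wall          = c(t2_mean = 54, t2_sd = 13, beta_mean = 500, beta_sd = 25),
    fibrous       = c(t2_mean = 56, t2_sd = 9, beta_mean = 500, beta_sd = 25),
    LRNC          = c(t2_mean = 37, t2_sd = 5, beta_mean = 500, beta_sd = 25),
    recent_IPH    = c(t2_mean = 107, t2_sd = 25, beta_mean = 500, beta_sd = 25),
    muscle        = c(t2_mean = 39, t2_sd = 6, beta_mean = 500, beta_sd = 25),
    calcification = c(t2_mean = NA, t2_sd = 0, beta_mean = 0, beta_sd = 0))
}

validate_phantom_spec <- function(spec) {
  te <- spec$te_grid_ms
  if (length(te) < 2 || any(te <= 0) || any(diff(te) <= 0))
    abort("`te_grid_ms` must be strictly increasing and positive.")
  if (spec$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (!(spec$first_echo_scale > 0 && spec$first_echo_scale <= 1))
    abort("`first_echo_scale` must lie in (0, 1].")
  if (spec$lumen_radius_px <= 0 || spec$wall_thickness_px <= 0 ||
      spec$pixel_size_mm <= 0)
    abort("Radii, wall thickness and pixel size must be positive.")
  for (p in spec$tissue_params) {
    if (!is.na(p[["t2_sd"]]) && p[["t2_sd"]] < 0)
      abort("Tissue T2 SDs must be non-negative.")
  }
  if (!spec$wall_tissue %in% names(spec$tissue_params))
    abort("`wall_tissue` has no entry in `tissue_params`.")
  outer <- spec$lumen_radius_px + spec$wall_thickness_px
  for (b in spec$component_blobs) {
    if (is.null(b$tissue) || !b$tissue %in% names(spec$tissue_params))
      abort("Each component blob needs a `tissue` present in `tissue_params`.")
    if (b$radius_px <= 0) abort("Blob radii must be positive.")
    d <- sqrt(sum((b$center - spec$lumen_center)^2))
    if (d - b$radius_px < spec$lumen_radius_px - 1e-9 ||
        d + b$radius_px > outer + 1e-9)
      abort(paste0("Component blob ('", b$tissue,
                   "') lies outside the wall annulus."))
  }
  if (!is.null(spec$muscle_blob)) {
    d <- sqrt(sum((spec$muscle_blob$center - spec$lumen_center)^2))
    if (d - spec$muscle_blob$radius_px < outer)
      abort("Muscle blob overlaps the vessel.")
  }
  invisible(spec)
}

pixel_distance <- function(grid_shape, center) {
  rows <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  cols <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2],
                 byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2)
}

#' Rasterize a phantom and draw its ground truth
#'
#' Builds the per-pixel tissue label map and draws per-pixel ground-truth
#' T2 and amplitude values from each tissue's Gaussian (T2 truncated below
#' at `t2_floor_ms`, amplitudes at 0). Lumen and background carry beta = 0;
#' calcification carries beta ~ 0 and no T2. Reproducible given
#' `spec$seed`; the label map depends only on the geometry, not on the
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom"` with `label_map` (character matrix),
#'   `truth_t2_map` and `truth_beta_map` (numeric matrices, `NA` where no
#'   T2 is defined), and the spec.
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape
  label <- matrix("background", gs[1], gs[2])
  d_lumen <- pixel_distance(gs, spec$lumen_center)
  outer <- spec$lumen_radius_px + spec$wall_thickness_px
  label[d_lumen <= outer] <- spec$wall_tissue
  label[d_lumen <= spec$lumen_radius_px] <- "lumen"
  if (!is.null(spec$muscle_blob)) {
    dm <- pixel_distance(gs, spec$muscle_blob$center)
    label[dm <= spec$muscle_blob$radius_px & label == "background"] <- "muscle"
  }
  in_annulus <- d_lumen <= outer & d_lumen > spec$lumen_radius_px
  for (b in spec$component_blobs) {  # last-listed wins on overlap
    db <- pixel_distance(gs, b$center)
    label[db <= b$radius_px & in_annulus] <- b$tissue
  }

  t2 <- matrix(NA_real_, gs[1], gs[2])
  beta <- matrix(0, gs[1], gs[2])
  withr::with_seed(spec$seed, {
    for (tis in names(spec$tissue_params)) {
      idx <- which(label == tis)
      if (!length(idx)) next
      p <- spec$tissue_params[[tis]]
      if (tis == "calcification" || is.na(p[["t2_mean"]])) {
        beta[idx] <- pmax(0, rnorm(length(idx), p[["beta_mean"]], p[["beta_sd"]]))
      } else {
        t2[idx] <- pmax(spec$t2_floor_ms,
                        rnorm(length(idx), p[["t2_mean"]], p[["t2_sd"]]))
        beta[idx] <- pmax(0, rnorm(length(idx), p[["beta_mean"]], p[["beta_sd"]]))
      }
    }
  })
  structure(list(label_map = label, truth_t2_map = t2, truth_beta_map = beta,
                 spec = spec),
            class = "phantom")
}

#' Simulate a multi-echo magnitude image series from a phantom
#'
#' The noise-free signal of a signal-bearing pixel at echo k is
#' `beta * exp(-TE_k / T2)`; lumen, background and calcification pixels are
#' (near) signal-free. The first echo is additionally multiplied by
#' `first_echo_scale` to emulate the primary-vs-stimulated-echo amplitude
#' mismatch, an optional smooth coil profile multiplies all echoes
#' identically, and magnitude (Rician) noise is formed as
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, noise_sd)`.
#'
#' @param phantom A [build_phantom()] result.
#' @param spec Optional [phantom_spec()]; defaults to the one stored in the
#'   phantom.
#' @return A list of class `"multiecho_stack"` with `stack` (rows x cols x
#'   echoes array), `te_ms`, `noise_sd` and `pixel_size_mm`.
#' @export
simulate_series <- function(phantom, spec = phantom$spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape
  te <- spec$te_grid_ms
  m <- length(te)
  stack <- array(0, c(gs[1], gs[2], m))
  beta <- phantom$truth_beta_map
  t2 <- phantom$truth_t2_map
  signal_px <- which(beta > 0 & is.finite(t2))
  for (k in seq_len(m)) {
    plane <- matrix(0, gs[1], gs[2])
    plane[signal_px] <- beta[signal_px] * exp(-te[k] / t2[signal_px])
    stack[, , k] <- plane
  }
  stack[, , 1] <- stack[, , 1] * spec$first_echo_scale
  if (spec$flow_artifact_amp > 0) {
    lum <- phantom$label_map == "lumen"
    p1 <- stack[, , 1]
    p1[lum] <- p1[lum] + spec$flow_artifact_amp
    stack[, , 1] <- p1
  }
  if (!is.null(spec$coil_profile)) {
    cp <- spec$coil_profile
    d <- pixel_distance(gs, cp$center)
    shade <- 1 + cp$amplitude * exp(-d^2 / (2 * cp$width_px^2))
    for (k in seq_len(m)) stack[, , k] <- stack[, , k] * shade
  }
  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed + 1L, {
      n <- length(stack)
      stack <- sqrt((stack + rnorm(n, 0, spec$noise_sd))^2 +
                      rnorm(n, 0, spec$noise_sd)^2)
      stack <- array(stack, c(gs[1], gs[2], m))
    })
  }
  structure(list(stack = stack, te_ms = te, noise_sd = spec$noise_sd,
                 pixel_size_mm = spec$pixel_size_mm),
            class = "multiecho_stack")
}

#' Standard masks of a phantom
#'
#' @param phantom A [build_phantom()] result.
#' @return List of logical matrices: `wall` (annulus including embedded
#'   components), `lumen`, `muscle`, `background`.
#' @export
phantom_masks <- function(phantom) {
  lab <- phantom$label_map
  wall_labels <- c("wall", "fibrous", "LRNC", "recent_IPH", "calcification")
  list(wall = matrix(lab %in% wall_labels, nrow(lab), ncol(lab)),
       lumen = lab == "lumen",
       muscle = lab == "muscle",
       background = lab == "background")
}

#' Noise SD that yields a target measured first-echo SNR
#'
#' Solves `snr = first_echo_scale * beta_mean * exp(-TE1/t2) / noise_sd`
#' for the noise SD, using a tissue's mean parameters.
#'
#' @param spec A [phantom_spec()].
#' @param snr Target SNR at the first echo (default 30, typical of normal
#'   carotid wall).
#' @param tissue Tissue label whose mean T2/beta define the signal.
#' @return Noise SD (same units as beta).
#' @export
noise_sd_for_first_echo_snr <- function(spec, snr = 30, tissue = spec$wall_tissue) {
  p <- spec$tissue_params[[tissue]]
  if (is.null(p) || is.na(p[["t2_mean"]])) abort("Tissue has no T2 mean.")
  spec$first_echo_scale * p[["beta_mean"]] *
    exp(-spec$te_grid_ms[1] / p[["t2_mean"]]) / snr
}
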