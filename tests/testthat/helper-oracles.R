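# Shared generators and independent oracles for the test suite.

TE8 <- 12.9 * (1:8)

# magnitude (Rician) sample of a noise-free signal vector
rician <- function(s, sd) sqrt((s + rnorm(length(s), 0, sd))^2 +
                                 rnorm(length(s), 0, sd)^2)

# one-voxel echo series; first_echo_scale emulates the primary-echo mismatch
make_series <- function(beta = 500, t2 = 50, te = TE8, noise_sd = 0,
                        first_echo_scale = 1) {
  s <- beta * exp(-te / t2)
  s[1] <- s[1] * first_echo_scale
  si <- if (noise_sd > 0) rician(s, noise_sd) else s
  tibble::tibble(te_ms = te, si = si)
}

# brute-force RSS minimum over a log-spaced (beta, T2) grid
grid_search_rss <- function(te, si, n_grid = 400,
                            beta_range = c(max(si) / 20, max(si) * 20),
                            t2_range = c(1, 2000)) {
  betas <- exp(seq(log(beta_range[1]), log(beta_range[2]), length.out = n_grid))
  t2s <- exp(seq(log(t2_range[1]), log(t2_range[2]), length.out = n_grid))
  E <- exp(-outer(t2s, te, function(t2, te) te / t2))  # n_grid x m
  sE <- E %*% si          # sum si * e
  EE <- rowSums(E^2)      # sum e^2
  ss <- sum(si^2)
  # rss(beta, t2) = ss - 2 beta sE + beta^2 EE, minimized over the grid
  rss <- outer(as.vector(sE), betas, function(a, b) -2 * b * a) +
    outer(as.vector(EE), betas, function(a, b) b^2 * a) + ss
  min(rss)
}

# MAP label changes located by brute-force scan (oracle for the analytic
# boundary roots)
scan_boundaries <- function(model, lo = 1, hi = 300, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  lab <- as.integer(carotidT2::map_classify(grid, model))
  idx <- which(diff(lab) != 0)
  (grid[idx] + grid[idx + 1]) / 2
}

# closed-form Bayes accuracy: P(correct) = sum_i prior_i * P(region_i | i),
# with regions read off a fine scan of the classifier
analytic_bayes_accuracy <- function(model, lo = 0.5, hi = 400) {
  cuts <- c(lo, scan_boundaries(model, lo, hi, 0.001), hi)
  mids <- (head(cuts, -1) + tail(cuts, -1)) / 2
  lab <- as.character(carotidT2::map_classify(mids, model))
  p <- model$params
  acc <- 0
  for (i in seq_len(nrow(p))) {
    own <- which(lab == p$class[i])
    mass <- sum(pnorm(cuts[own + 1], p$mu_ms[i], p$sd_ms[i]) -
                  pnorm(cuts[own], p$mu_ms[i], p$sd_ms[i]))
    acc <- acc + p$prior[i] * mass
  }
  acc
}

# training table drawn from the in-vivo class distributions
paper_training <- function(n = 100) {
  tibble::tibble(
    class = rep(c("LRNC", "fibrous", "recent_IPH"), each = n),
    t2_ms = c(rnorm(n, 37, 5), rnorm(n, 56, 9), rnorm(n, 107, 25)))
}

# class model at the exact generating parameters (no training noise)
paper_model <- function() {
  carotidT2::class_model(c("LRNC", "fibrous", "recent_IPH"),
                         mu_ms = c(37, 56, 107), sd_ms = c(5, 9, 25))
}

# a small, quick diseased phantom for pipeline tests
small_phantom_spec <- function(seed = 1L, noise_sd = 11.25,
                               component_blobs = list(
                                 list(tissue = "LRNC", center = c(24.5, 33.5),
                                      radius_px = 4),
                                 list(tissue = "recent_IPH",
                                      center = c(15.5, 24.5), radius_px = 4),
                                 list(tissue = "calcification",
                                      center = c(31, 17), radius_px = 2.5)),
                               ...) {
  phantom_spec(grid_shape = c(48L, 48L), lumen_radius_px = 4,
               wall_thickness_px = 10,
               component_blobs = component_blobs,
               muscle_blob = list(center = c(8, 8), radius_px = 4),
               noise_sd = noise_sd, seed = seed, ...)
}

# 4-neighbour erosion of a logical mask (interior pixels)
erode_mask <- function(m) {
  m & rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
    cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)])
}
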