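test_that("training recovers the generating class parameters", {
  set.seed(12)
  tr <- paper_training(100)
  m <- train_class_model(tr)
  p <- tidy(m)
  expect_identical(p$class, c("LRNC", "fibrous", "recent_IPH"))
  expect_identical(p$n_train, rep(100L, 3))
  gen_mu <- c(37, 56, 107)
  gen_sd <- c(5, 9, 25)
  # mean within 3 SEs (sd/sqrt(n)); sd within 3 SEs (sd/sqrt(2n))
  expect_true(all(abs(p$mu_ms - gen_mu) < 3 * gen_sd / sqrt(100)))
  expect_true(all(abs(p$sd_ms - gen_sd) < 3 * gen_sd / sqrt(200)))
  expect_equal(sum(p$prior), 1)
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_class_model(
    tibble::tibble(class = c("LRNC", "fibrous", "fibrous"),
                   t2_ms = c(37, 55, 57))), "at least 2")
  expect_error(train_class_model(
    tibble::tibble(class = rep(c("LRNC", "fibrous"), each = 2),
                   t2_ms = c(37, 37, 55, 57))), "zero T2 variance")
  expect_error(train_class_model(
    tibble::tibble(class = rep("LRNC", 3), t2_ms = c(-1, 35, 40))),
    "positive")
  # explicit priors are normalized
  tr <- tibble::tibble(class = rep(c("LRNC", "fibrous", "recent_IPH"), each = 2),
                       t2_ms = c(35, 39, 52, 60, 100, 114))
  m <- train_class_model(tr, priors = c(0.5, 0.3, 0.21))
  expect_equal(sum(tidy(m)$prior), 1)
  expect_equal(tidy(m)$prior, c(0.5, 0.3, 0.21) / 1.01)
})

test_that("posteriors are normalized and follow the densities", {
  m <- paper_model()
  set.seed(5)
  t2 <- runif(1000, 2, 300)
  post <- class_posterior(t2, m)
  expect_equal(unname(rowSums(post)), rep(1, 1000))
  # at the LRNC mean the LRNC posterior dominates
  expect_identical(names(which.max(class_posterior(37, m)[1, ])), "LRNC")
  # far right tail belongs to recent IPH
  expect_identical(as.character(map_classify(200, m)), "recent_IPH")
  # two identical classes split the posterior evenly
  m2 <- class_model(c("a", "b"), c(50, 50), c(10, 10))
  expect_equal(unname(class_posterior(60, m2)[1, ]), c(0.5, 0.5))
  # ties break by class order
  expect_identical(as.character(map_classify(60, m2)), "a")
})

test_that("equal-SD classes split at the midpoint of their means", {
  m <- class_model(c("lo", "hi"), c(40, 60), c(10, 10))
  b <- decision_boundaries(m)
  expect_equal(b$t2_ms, 50)
  expect_identical(as.character(map_classify(49.99, m)), "lo")
  expect_identical(as.character(map_classify(50.01, m)), "hi")
})

test_that("analytic boundaries coincide with a fine classifier scan", {
  models <- list(
    paper_model(),
    class_model(c("LRNC", "fibrous", "recent_IPH"), c(37, 56, 107),
                c(5, 9, 25), prior = c(0.2, 0.6, 0.2)),
    class_model(c("a", "b", "c"), c(30, 50, 65), c(12, 6, 20),
                prior = c(0.45, 0.35, 0.2)))
  for (m in models) {
    analytic <- decision_boundaries(m, c(1, 300))$t2_ms
    scanned <- scan_boundaries(m, 1, 300, 0.001)
    expect_identical(length(analytic), length(scanned))
    expect_lt(max(abs(analytic - scanned)), 0.001)
  }
})

test_that("raising a class prior never shrinks its decision region", {
  grid <- seq(1, 300, by = 0.25)
  base <- map_classify(grid, paper_model()) == "fibrous"
  up <- map_classify(grid, class_model(
    c("LRNC", "fibrous", "recent_IPH"), c(37, 56, 107), c(5, 9, 25),
    prior = c(0.25, 0.5, 0.25))) == "fibrous"
  expect_true(all(up[base]))
  expect_gt(sum(up), sum(base))
})

test_that("classifier accuracy matches the closed-form Bayes accuracy", {
  set.seed(14)
  m <- train_class_model(paper_training(100))
  n <- 1e4
  cls <- sample(1:3, n, replace = TRUE)
  p <- tidy(m)
  draws <- pmax(rnorm(n, p$mu_ms[cls], p$sd_ms[cls]), 1)
  emp <- mean(as.integer(map_classify(draws, m)) == cls)
  ana <- analytic_bayes_accuracy(m)
  expect_lt(abs(emp - ana), 3 * sqrt(ana * (1 - ana) / n))
})

test_that("calcification rule flags signal-free wall voxels only", {
  spec <- small_phantom_spec(seed = 4L)
  ph <- build_phantom(spec)
  ser <- simulate_series(ph)
  wall <- phantom_masks(ph)$wall
  map <- fit_t2_map(ser, wall, spec$noise_sd)
  calc <- detect_calcification(map, wall)
  truth <- ph$label_map == "calcification"
  # the vast majority of signal-free pixels are flagged (the measured
  # noise-floor value sits under the 2-sigma threshold ~ 86-95% of the time)
  expect_gte(mean(calc[truth]), 0.8)
  # no accepted signal-tissue voxel is dragged in
  expect_identical(sum(calc & map$accept_mask), 0L)
  # rule arithmetic: a fibrous voxel at 3 sigma synthetic SNR stays clear
  syn <- synthetic_image(map)
  fib_ok <- ph$label_map == "fibrous" & map$accept_mask
  expect_true(all(!calc[fib_ok & !is.na(syn$snr) & syn$snr >= 3]))
  # empty wall mask gives an empty calcification mask
  none <- detect_calcification(map, matrix(FALSE, 48, 48))
  expect_identical(sum(none), 0L)
})

test_that("segmentation pipeline orders rules and stores posteriors", {
  set.seed(26)
  spec <- small_phantom_spec(seed = 7L)
  ph <- build_phantom(spec)
  ser <- simulate_series(ph)
  wall <- phantom_masks(ph)$wall
  map <- fit_t2_map(ser, wall, spec$noise_sd)
  model <- train_class_model(paper_training(100))
  seg <- segment_plaque(map, wall, model)
  lab <- seg$label_map
  # outside stays outside; wall voxels carry exactly one outcome
  expect_true(all(lab[!wall] == "outside"))
  expect_true(all(lab[wall] %in%
                    c(model$classes, "calcification", "rejected")))
  # posteriors: sum to 1 where classified, absent on calcification
  cls_px <- which(matrix(lab %in% model$classes, 48, 48))
  psum <- apply(seg$posterior, c(1, 2), sum)
  expect_equal(unname(psum[cls_px]), rep(1, length(cls_px)))
  expect_true(all(is.na(psum[lab == "calcification"])))
  # counts table adds up to the wall
  expect_identical(sum(tidy(seg)$n_voxels), sum(wall))
  # majority of the fibrous annulus is labelled fibrous
  fib <- ph$label_map == "fibrous"
  expect_gt(mean(lab[fib] == "fibrous"), 0.7)
  expect_error(segment_plaque(map, wall, model = list()), "class_model")
})

test_that("uniform fibrous wall classifies almost entirely as fibrous", {
  tp <- default_tissue_params()
  tp$fibrous["t2_sd"] <- 0
  spec <- small_phantom_spec(noise_sd = 0, tissue_params = tp,
                             component_blobs = list())
  ph <- build_phantom(spec)
  ser <- simulate_series(ph)
  wall <- phantom_masks(ph)$wall
  map <- fit_t2_map(ser, wall, noise_sd = 0)
  seg <- segment_plaque(map, wall, paper_model())
  expect_true(all(seg$label_map[wall] == "fibrous"))
})

test_that("with no accepted voxels nothing is classified", {
  spec <- small_phantom_spec(seed = 8L)
  ph <- build_phantom(spec)
  ser <- simulate_series(ph)
  wall <- phantom_masks(ph)$wall
  map <- fit_t2_map(ser, wall, spec$noise_sd)
  map$accept_mask[] <- FALSE
  map$t2_ms[] <- NA_real_
  seg <- segment_plaque(map, wall, paper_model())
  counts <- tidy(seg)
  expect_identical(sum(counts$n_voxels[counts$class %in%
                                         paper_model()$classes]), 0L)
  expect_true(all(seg$label_map[wall] %in% c("calcification", "rejected")))
})

test_that("optional IPH component filter removes small islands only", {
  set.seed(33)
  spec <- small_phantom_spec(seed = 10L)
  ph <- build_phantom(spec)
  ser <- simulate_series(ph)
  wall <- phantom_masks(ph)$wall
  map <- fit_t2_map(ser, wall, spec$noise_sd)
  model <- paper_model()
  seg_off <- segment_plaque(map, wall, model)
  seg_on <- segment_plaque(map, wall, model, min_iph_component = 10L)
  n_off <- sum(seg_off$label_map == "recent_IPH")
  n_on <- sum(seg_on$label_map == "recent_IPH")
  expect_lte(n_on, n_off)
  # the large genuine IPH blob survives the filter
  iph_core <- erode_mask(ph$label_map == "recent_IPH")
  expect_gt(mean(seg_on$label_map[iph_core] == "recent_IPH"), 0.7)
  # relabelled voxels went to their runner-up class, not to "rejected"
  moved <- seg_off$label_map == "recent_IPH" & seg_on$label_map != "recent_IPH"
  expect_true(all(seg_on$label_map[moved] %in% model$classes))
})
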