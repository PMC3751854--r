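#' Train a Gaussian naive-Bayes class model over T2
#'
#' Estimates, for each tissue class, the mean and SD (n-1 denominator) of
#' T2 from labelled training voxels (in the original analysis roughly 100
#' manually selected voxels per class), and attaches prior probabilities
#' (equal by default). The classifier is
#' `P(C_i | T2) = P(C_i) * P(T2 | C_i)` with Gaussian class likelihoods,
#' combined with the maximum-a-posteriori rule ([map_classify()]).
#'
#' @param training Data frame with columns `class` and `t2_ms` (positive);
#'   see [read_training_table()] for the file format.
#' @param priors Optional per-class prior probabilities, in class order;
#'   normalized if they do not sum exactly to 1. Default: equal.
#' @param classes Optional class order. Defaults to the canonical
#'   `LRNC < fibrous < recent_IPH` order for those labels, otherwise order
#'   of appearance. The order is also the MAP tie-break.
#' @return An object of class `"class_model"` wrapping a tibble with
#'   columns `class`, `mu_ms`, `sd_ms`, `prior`, `n_train`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- tibble::tibble(
#'   class = rep(c("LRNC", "fibrous", "recent_IPH"), each = 100),
#'   t2_ms = c(rnorm(100, 37, 5), rnorm(100, 56, 9), rnorm(100, 107, 25)))
#' train_class_model(tr)
train_class_model <- function(training, priors = NULL, classes = NULL) {
  if (!is.data.frame(training) || !all(c("class", "t2_ms") %in% names(training)))
    abort("`training` needs columns `class` and `t2_ms`.")
  if (any(training$t2_ms <= 0)) abort("Training T2 values must be positive.")
  found <- unique(as.character(training$class))
  if (is.null(classes)) {
    canonical <- c("LRNC", "fibrous", "recent_IPH")
    classes <- if (all(found %in% canonical)) canonical[canonical %in% found]
               else found
  }
  if (!all(found %in% classes)) abort("`training` has labels not in `classes`.")
  stats_tbl <- training |>
    dplyr::mutate(class = factor(.data$class, levels = classes)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mu_ms = mean(.data$t2_ms), sd_ms = sd(.data$t2_ms),
                     n_train = dplyr::n(), .groups = "drop")
  if (nrow(stats_tbl) < length(classes))
    abort("Every class in `classes` needs training voxels.")
  if (any(stats_tbl$n_train < 2))
    abort("Each class needs at least 2 training voxels.")
  if (any(!is.finite(stats_tbl$sd_ms)) || any(stats_tbl$sd_ms <= 0))
    abort("A class has zero T2 variance; cannot form its Gaussian.")
  k <- length(classes)
  if (is.null(priors)) priors <- rep(1 / k, k)
  if (length(priors) != k || any(priors <= 0))
    abort("`priors` must be one positive value per class.")
  priors <- priors / sum(priors)
  out <- dplyr::mutate(stats_tbl, prior = priors, class = as.character(.data$class)) |>
    dplyr::select("class", "mu_ms", "sd_ms", "prior", "n_train")
  structure(list(params = out, classes = classes), class = "class_model")
}

#' Build a class model from explicit parameters
#'
#' Constructs the Gaussian naive-Bayes model directly from per-class means
#' and SDs, bypassing training data — useful when the class distributions
#' are known (e.g. literature values) rather than estimated.
#'
#' @param classes Ordered class labels.
#' @param mu_ms,sd_ms Per-class Gaussian mean and SD of T2 (ms).
#' @param prior Per-class priors (default equal); normalized.
#' @return An object of class `"class_model"`.
#' @export
#' @examples
#' class_model(c("LRNC", "fibrous", "recent_IPH"),
#'             mu_ms = c(37, 56, 107), sd_ms = c(5, 9, 25))
class_model <- function(classes, mu_ms, sd_ms, prior = NULL) {
  k <- length(classes)
  if (length(mu_ms) != k || length(sd_ms) != k)
    abort("`mu_ms` and `sd_ms` must have one value per class.")
  if (any(sd_ms <= 0)) abort("Class SDs must be positive.")
  if (is.null(prior)) prior <- rep(1 / k, k)
  if (length(prior) != k || any(prior <= 0))
    abort("`prior` must be one positive value per class.")
  prior <- prior / sum(prior)
  structure(list(params = tibble(class = as.character(classes),
                                 mu_ms = as.numeric(mu_ms),
                                 sd_ms = as.numeric(sd_ms),
                                 prior = prior, n_train = NA_integer_),
                 classes = as.character(classes)),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat("Gaussian naive-Bayes T2 class model\n")
  print(x$params)
  invisible(x)
}

#' Posterior class probabilities for T2 values
#'
#' `P(C_i | T2)` is proportional to `prior_i * phi((T2 - mu_i)/sd_i)/sd_i`
#' and is normalized to sum to 1 over the classes. Computed on the log
#' scale for numerical stability.
#'
#' @param t2_ms Positive T2 value(s) in ms.
#' @param model A [train_class_model()] result.
#' @return Matrix with one row per T2 value and one named column per class;
#'   rows sum to 1.
#' @export
class_posterior <- function(t2_ms, model) {
  if (any(t2_ms <= 0)) abort("`t2_ms` must be positive.")
  p <- model$params
  logp <- vapply(seq_len(nrow(p)), function(i) {
    log(p$prior[i]) + dnorm(t2_ms, p$mu_ms[i], p$sd_ms[i], log = TRUE)
  }, numeric(length(t2_ms)))
  logp <- matrix(logp, nrow = length(t2_ms),
                 dimnames = list(NULL, p$class))
  logp <- logp - apply(logp, 1, max)
  pr <- exp(logp)
  pr / rowSums(pr)
}

#' Maximum-a-posteriori class assignment
#'
#' Assigns each T2 value to the class with the highest posterior
#' probability; exact ties (measure zero for continuous T2) break by class
#' order.
#'
#' @inheritParams class_posterior
#' @return Factor of class labels with levels in class order.
#' @export
#' @examples
#' m <- train_class_model(tibble::tibble(
#'   class = rep(c("LRNC", "fibrous"), each = 2),
#'   t2_ms = c(36, 38, 55, 57)))
#' map_classify(c(37, 56), m)
map_classify <- function(t2_ms, model) {
  post <- class_posterior(t2_ms, model)
  lab <- model$params$class[max.col(post, ties.method = "first")]
  factor(lab, levels = model$classes)
}

#' Analytic MAP decision boundaries over T2
#'
#' For each pair of classes the equality of posterior log-densities
#' `log prior - log sd - (t - mu)^2 / (2 sd^2)` is a quadratic (linear for
#' equal SDs) in T2; its real roots are the only points where the MAP
#' label can change. The function returns the roots inside `range_ms` at
#' which the assigned label actually changes.
#'
#' @param model A [train_class_model()] result.
#' @param range_ms T2 interval to report boundaries in.
#' @return Tibble with `t2_ms` (sorted boundary), `left_class`,
#'   `right_class`.
#' @export
decision_boundaries <- function(model, range_ms = c(1, 2000)) {
  p <- model$params
  k <- nrow(p)
  roots <- numeric(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s1 <- p$sd_ms[i]; s2 <- p$sd_ms[j]
      m1 <- p$mu_ms[i]; m2 <- p$mu_ms[j]
      a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
      b <- m1 / s1^2 - m2 / s2^2
      cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) +
        log(p$prior[i] * s2 / (p$prior[j] * s1))
      if (abs(a) < 1e-14) {
        if (abs(b) > 1e-14) roots <- c(roots, -cc / b)
      } else {
        disc <- b^2 - 4 * a * cc
        if (disc >= 0) roots <- c(roots, (-b + c(-1, 1) * sqrt(disc)) / (2 * a))
      }
    }
  }
  roots <- sort(unique(roots[roots > range_ms[1] & roots < range_ms[2]]))
  if (!length(roots)) {
    return(tibble(t2_ms = numeric(0), left_class = character(0),
                  right_class = character(0)))
  }
  eps <- 1e-9 * pmax(1, roots)
  left <- as.character(map_classify(pmax(range_ms[1], roots - eps), model))
  right <- as.character(map_classify(pmin(range_ms[2], roots + eps), model))
  keep <- left != right
  tibble(t2_ms = roots[keep], left_class = left[keep],
         right_class = right[keep])
}

#' Detect calcification on the synthetic PDW image
#'
#' Calcified voxels carry almost no water signal; inside the vessel wall
#' they are identified as voxels whose synthetic proton-density-weighted
#' intensity (the fitted decay curve evaluated at a short TE, default
#' 14 ms, with first-echo fallback for voxels without a usable fit) has
#' SNR < 2.
#'
#' @param t2_map A [fit_t2_map()] result covering the wall.
#' @param wall_mask Logical matrix of vessel-wall voxels.
#' @param noise_sd SNR denominator; defaults to the map's.
#' @param te_query_ms Query TE in ms (default from the map's config).
#' @param mode Synthetic-image mode override (see [synthetic_image()]).
#' @return Logical matrix: `TRUE` for wall voxels flagged as calcification.
#' @export
detect_calcification <- function(t2_map, wall_mask,
                                 noise_sd = t2_map$noise_sd,
                                 te_query_ms = t2_map$config$pdw_te_ms,
                                 mode = NULL) {
  if (!all(dim(wall_mask) == dim(t2_map$t2_ms)))
    abort("`wall_mask` is not on the map grid.")
  if (!is.logical(wall_mask)) wall_mask <- wall_mask > 0
  syn <- synthetic_image(t2_map, te_query_ms, noise_sd, mode)
  low <- !is.na(syn$snr) & syn$snr < 2
  wall_mask & low
}

#' Segment accepted wall voxels into plaque components
#'
#' The full segmentation pipeline on a fitted T2 map: (1) calcification is
#' removed by the synthetic-PDW SNR < 2 rule; (2) remaining wall voxels
#' whose fit was rejected are marked `rejected`; (3) every other wall
#' voxel is assigned by the MAP rule to LRNC, fibrous tissue or recent
#' IPH, with posteriors stored. Calcified voxels never carry posteriors.
#'
#' @inheritParams detect_calcification
#' @param model A [train_class_model()] result.
#' @param config A [fit_config()] (controls the synthetic-PDW rule);
#'   defaults to the map's.
#' @param min_iph_component Optional minimum 4-connected component size for
#'   `recent_IPH`; smaller islands (typically isolated T2 overestimates)
#'   are relabelled to the runner-up class. 0 (default) disables the
#'   filter.
#' @return An object of class `"plaque_segmentation"`: `label_map`
#'   (character matrix over {outside, calcification, rejected, and the
#'   model classes}), `posterior` (rows x cols x classes array), `counts`
#'   tibble, and the model.
#' @export
segment_plaque <- function(t2_map, wall_mask, model,
                           noise_sd = t2_map$noise_sd,
                           config = t2_map$config,
                           min_iph_component = 0L) {
  if (!inherits(model, "class_model")) abort("`model` must be a class_model.")
  if (!all(dim(wall_mask) == dim(t2_map$t2_ms)))
    abort("`wall_mask` is not on the map grid.")
  if (!is.logical(wall_mask)) wall_mask <- wall_mask > 0
  dims <- dim(t2_map$t2_ms)
  calc <- detect_calcification(t2_map, wall_mask, noise_sd,
                               config$pdw_te_ms, config$pdw_mode)
  label <- matrix("outside", dims[1], dims[2])
  label[wall_mask] <- "rejected"
  label[calc] <- "calcification"
  classify_px <- which(wall_mask & !calc & t2_map$accept_mask)
  k <- length(model$classes)
  posterior <- array(NA_real_, c(dims[1], dims[2], k),
                     dimnames = list(NULL, NULL, model$classes))
  if (length(classify_px)) {
    t2v <- t2_map$t2_ms[classify_px]
    post <- class_posterior(t2v, model)
    label[classify_px] <- as.character(map_classify(t2v, model))
    for (j in seq_len(k)) {
      plane <- posterior[, , j]
      plane[classify_px] <- post[, j]
      posterior[, , j] <- plane
    }
  }
  if (min_iph_component > 0 && "recent_IPH" %in% model$classes)
    label <- filter_small_components(label, "recent_IPH", min_iph_component,
                                     posterior, model)
  counts <- tibble(class = c(model$classes, "calcification", "rejected")) |>
    dplyr::mutate(n_voxels = vapply(.data$class, function(cl) sum(label == cl),
                                    integer(1)))
  structure(list(label_map = label, posterior = posterior, counts = counts,
                 model = model, wall_mask = wall_mask),
            class = "plaque_segmentation")
}

# Relabel 4-connected recent_IPH islands smaller than min_size to the
# runner-up posterior class.
filter_small_components <- function(label, class, min_size, posterior, model) {
  target <- label == class
  if (!any(target)) return(label)
  dims <- dim(label)
  comp <- matrix(0L, dims[1], dims[2])
  current <- 0L
  for (start in which(target & comp == 0L)) {
    if (comp[start] != 0L) next
    current <- current + 1L
    queue <- start
    comp[start] <- current
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      r <- (v - 1L) %% dims[1] + 1L
      cl <- (v - 1L) %/% dims[1] + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- cl + d[2]
        if (rr < 1 || cc < 1 || rr > dims[1] || cc > dims[2]) next
        w <- (cc - 1L) * dims[1] + rr
        if (target[w] && comp[w] == 0L) {
          comp[w] <- current
          queue <- c(queue, w)
        }
      }
    }
  }
  sizes <- tabulate(comp[comp > 0L])
  small <- which(comp > 0L & sizes[pmax(comp, 1L)] < min_size)
  if (length(small)) {
    ord <- match(class, model$classes)
    for (v in small) {
      post <- posterior[(v - 1L) %% dims[1] + 1L, (v - 1L) %/% dims[1] + 1L, ]
      post[ord] <- -Inf
      label[v] <- model$classes[which.max(post)]
    }
  }
  label
}

#' @export
print.plaque_segmentation <- function(x, ...) {
  cat("Plaque segmentation (Gaussian Bayes + MAP)\n")
  print(x$counts)
  invisible(x)
}
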