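#' Per-class T2 summary of a segmentation
#'
#' Voxel count, sample mean and sample SD (n-1 denominator) of the
#' accepted T2 values in each segmented tissue class. Calcification has no
#' valid T2, so it reports a count only; classes with fewer than two
#' voxels report an undefined (NA) SD, and empty classes an undefined
#' mean.
#'
#' @param segmentation A [segment_plaque()] result.
#' @param t2_map The [fit_t2_map()] result the segmentation was built on.
#' @return Tibble with columns `class`, `n_voxels`, `mean_ms`, `sd_ms`.
#' @export
class_summary <- function(segmentation, t2_map) {
  if (!all(dim(segmentation$label_map) == dim(t2_map$t2_ms)))
    abort("Segmentation and map are not on the same grid.")
  lab <- segmentation$label_map
  classes <- segmentation$model$classes
  rows <- lapply(classes, function(cl) {
    v <- t2_map$t2_ms[lab == cl]
    v <- v[is.finite(v)]
    tibble(class = cl, n_voxels = length(v),
           mean_ms = if (length(v)) mean(v) else NA_real_,
           sd_ms = if (length(v) >= 2) sd(v) else NA_real_)
  })
  dplyr::bind_rows(rows) |>
    dplyr::bind_rows(tibble(class = "calcification",
                            n_voxels = sum(lab == "calcification"),
                            mean_ms = NA_real_, sd_ms = NA_real_))
}

#' Cross-tabulate two raters' ordered categorical ratings
#'
#' @param ratings_a,ratings_b Equal-length vectors of category labels
#'   (rater A on rows, rater B on columns).
#' @param categories Ordered category labels; every rating must be one of
#'   them. Categories with zero margin are retained.
#' @return Square integer matrix of counts with `categories` as dimnames.
#' @export
#' @examples
#' tabulate_agreement(c("Normal", "III"), c("Normal", "III"),
#'                    c("Normal", "III", "IV-V"))
tabulate_agreement <- function(ratings_a, ratings_b, categories) {
  if (length(ratings_a) != length(ratings_b))
    abort("Rating vectors must have equal length.")
  if (!length(ratings_a)) abort("Rating vectors are empty.")
  bad <- setdiff(unique(c(ratings_a, ratings_b)), categories)
  if (length(bad))
    abort(paste0("Unknown categories: ", paste(bad, collapse = ", ")))
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  m <- table(fa, fb)
  matrix(as.integer(m), nrow = length(categories),
         dimnames = list(categories, categories))
}

check_agreement_table <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) abort("Agreement table must be square.")
  if (any(x < 0)) abort("Agreement counts must be non-negative.")
  if (sum(x) == 0) abort("Agreement table is empty (N = 0).")
  x
}

#' Percent agreement of a cross-classification
#'
#' The fraction of paired ratings on the diagonal, trace(X)/N.
#'
#' @param x Square matrix of counts (rows = rater A, cols = rater B).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' percent_agreement(carotid_aha_table())  # 28/37
percent_agreement <- function(x) {
  x <- check_agreement_table(x)
  sum(diag(x)) / sum(x)
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace(X)/N` and chance agreement
#' `p_e = sum_i row_i * col_i / N^2`. Linear and quadratic weighting over
#' the ordered categories are available but off by default (the unweighted
#' form is the conventional report for AHA plaque-type tables).
#'
#' @param x Square matrix of counts (rows = rater A, cols = rater B).
#' @param weights `"unweighted"` (default), `"linear"` or `"quadratic"`.
#' @return Kappa; `NaN` (with a warning) when chance agreement is 1.
#' @export
#' @examples
#' round(cohens_kappa(carotid_aha_table()), 2)  # 0.68
cohens_kappa <- function(x, weights = c("unweighted", "linear", "quadratic")) {
  weights <- match.arg(weights)
  x <- check_agreement_table(x)
  k <- nrow(x)
  idx <- abs(outer(seq_len(k), seq_len(k), "-"))
  v <- switch(weights,
              unweighted = (idx == 0) * 1,
              linear = 1 - idx / max(1, k - 1),
              quadratic = 1 - (idx / max(1, k - 1))^2)
  n <- sum(x)
  po <- sum(v * x) / n
  pe <- sum(v * outer(rowSums(x), colSums(x))) / n^2
  if (abs(1 - pe) < 1e-12) {
    warn("Chance agreement is 1; kappa is undefined.")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Agreement summary statistics
#'
#' @param x Square matrix of counts, or two rating vectors plus
#'   `categories` (passed to [tabulate_agreement()]).
#' @param ratings_b,categories See [tabulate_agreement()].
#' @return Tibble with `n`, `percent_agreement` (in percent), `kappa`.
#' @export
agreement_stats <- function(x, ratings_b = NULL, categories = NULL) {
  if (!is.null(ratings_b)) x <- tabulate_agreement(x, ratings_b, categories)
  x <- check_agreement_table(x)
  tibble(n = sum(x),
         percent_agreement = 100 * percent_agreement(x),
         kappa = cohens_kappa(x))
}

#' Example inter-reader AHA plaque-type table
#'
#' Cross-classification of 37 carotid arteries from 15 atherosclerotic
#' patients by two readers applying the CMR-modified AHA plaque-type
#' scheme, one reading conventional multicontrast CMR (rows) and the other
#' T2 maps plus TOF angiography (columns). Categories are ordered Normal,
#' III, IV-V, VI, VII, VIII. The table ships as plain CSV under
#' `inst/extdata/aha_reader_table.csv`.
#'
#' @return 6 x 6 integer matrix of counts (N = 37).
#' @export
#' @examples
#' agreement_stats(carotid_aha_table())
carotid_aha_table <- function() {
  path <- system.file("extdata", "aha_reader_table.csv",
                      package = "carotidT2", mustWork = TRUE)
  read_agreement_table(path)
}

#' Read an agreement-count matrix from CSV
#'
#' Expects a header of category names for rater B and a first column
#' `rater_a` of category names, one row per rater-A category.
#'
#' @param path CSV file path.
#' @return Square integer matrix with category dimnames.
#' @export
read_agreement_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "rater_a")
    abort("First column of an agreement table CSV must be `rater_a`.")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$rater_a
  storage.mode(m) <- "integer"
  check_agreement_table(m)
}
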