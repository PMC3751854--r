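#' Integer codes used in label-map images
#'
#' NIfTI label maps store tissue labels as integers; this table is the
#' documented code book.
#'
#' @return Named integer vector (label -> code).
#' @export
label_codes <- function() {
  c(background = 0L, lumen = 1L, wall = 2L, fibrous = 3L, LRNC = 4L,
    recent_IPH = 5L, calcification = 6L, muscle = 7L,
    outside = 8L, rejected = 9L)
}

encode_labels <- function(label_map) {
  codes <- label_codes()
  m <- matrix(codes[label_map], nrow(label_map), ncol(label_map))
  storage.mode(m) <- "integer"
  m
}

decode_labels <- function(code_map) {
  codes <- label_codes()
  matrix(names(codes)[match(as.integer(code_map), codes)],
         nrow(code_map), ncol(code_map))
}

#' Read and write a multi-echo series as NIfTI plus a TE sidecar
#'
#' The echo stack goes to a NIfTI volume (echo index as the third
#' dimension, stored as float64 so the round trip is lossless within
#' floating point); the TE vector and noise SD go to a JSON sidecar named
#' `<image>.json` with key `te_ms` (volumetric headers are too dialect-
#' dependent to carry the TE grid portably).
#'
#' @param series A `"multiecho_stack"` (list with `stack`, `te_ms`,
#'   optional `noise_sd`, `pixel_size_mm`).
#' @param path Path of the `.nii` file (the sidecar is derived from it).
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a `"multiecho_stack"`. Reading errors if the sidecar TE count
#'   does not match the echo dimension.
#' @export
write_series <- function(series, path) {
  stack <- series$stack
  if (length(dim(stack)) != 3) abort("`series$stack` must be 3-D.")
  if (dim(stack)[3] != length(series$te_ms))
    abort("TE count does not match the echo dimension.")
  RNifti::writeNifti(RNifti::asNifti(stack, datatype = "double"), path)
  jsonlite::write_json(
    list(te_ms = series$te_ms,
         noise_sd = series$noise_sd %||% NA_real_,
         pixel_size_mm = series$pixel_size_mm %||% NA_real_),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' @rdname write_series
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  stack <- array(as.numeric(img), dim(img))
  meta_file <- sidecar_path(path)
  if (!file.exists(meta_file))
    abort(paste0("TE sidecar not found: ", meta_file))
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  te <- as.numeric(meta$te_ms)
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  if (dim(stack)[3] != length(te))
    abort(sprintf("TE count (%d) does not match echo count (%d).",
                  length(te), dim(stack)[3]))
  structure(list(stack = stack, te_ms = te,
                 noise_sd = suppressWarnings(as.numeric(meta$noise_sd[1])),
                 pixel_size_mm = suppressWarnings(as.numeric(meta$pixel_size_mm[1]))),
            class = "multiecho_stack")
}

write_mask <- function(mask, path) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), path)
  invisible(path)
}

read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  matrix(as.integer(img) > 0, dim(img)[1], dim(img)[2])
}

read_image_matrix <- function(path) {
  img <- RNifti::readNifti(path)
  matrix(as.numeric(img), dim(img)[1], dim(img)[2])
}

#' Write a phantom fixture bundle to a directory
#'
#' Writes everything a downstream run needs: `series.nii` (+ TE sidecar),
#' `label_map.nii` (integer codes of [label_codes()]), `truth_t2.nii`,
#' `truth_beta.nii`, the four standard masks, and the phantom spec as
#' `spec.json`. `read_fixture_bundle()` reverses the operation; the round
#' trip is lossless within floating point.
#'
#' @param phantom A [build_phantom()] result.
#' @param series The matching [simulate_series()] result.
#' @param out_dir Output directory (created if needed).
#' @return `write_fixture_bundle()` returns `out_dir` invisibly;
#'   `read_fixture_bundle()` returns a list with `series`, `label_map`,
#'   `truth_t2_map`, `truth_beta_map`, `masks`, `spec` (plain list).
#' @export
write_fixture_bundle <- function(phantom, series, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create: ", out_dir))
  write_series(series, file.path(out_dir, "series.nii"))
  RNifti::writeNifti(RNifti::asNifti(encode_labels(phantom$label_map),
                                     datatype = "int16"),
                     file.path(out_dir, "label_map.nii"))
  t2 <- phantom$truth_t2_map
  t2[!is.finite(t2)] <- -1  # NA encoded as -1 (no valid T2)
  RNifti::writeNifti(RNifti::asNifti(t2, datatype = "double"),
                     file.path(out_dir, "truth_t2.nii"))
  RNifti::writeNifti(RNifti::asNifti(phantom$truth_beta_map, datatype = "double"),
                     file.path(out_dir, "truth_beta.nii"))
  masks <- phantom_masks(phantom)
  for (nm in names(masks))
    write_mask(masks[[nm]], file.path(out_dir, paste0(nm, "_mask.nii")))
  spec <- phantom$spec
  spec_json <- spec[setdiff(names(spec), "tissue_params")]
  spec_json$tissue_params <- lapply(spec$tissue_params, as.list)
  class(spec_json) <- NULL
  jsonlite::write_json(spec_json, file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(out_dir) {
  series <- read_series(file.path(out_dir, "series.nii"))
  label <- decode_labels(read_image_matrix(file.path(out_dir, "label_map.nii")))
  t2 <- read_image_matrix(file.path(out_dir, "truth_t2.nii"))
  t2[t2 < 0] <- NA_real_
  beta <- read_image_matrix(file.path(out_dir, "truth_beta.nii"))
  masks <- list()
  for (nm in c("wall", "lumen", "muscle", "background")) {
    f <- file.path(out_dir, paste0(nm, "_mask.nii"))
    if (file.exists(f)) masks[[nm]] <- read_mask(f)
  }
  spec <- jsonlite::read_json(file.path(out_dir, "spec.json"),
                              simplifyVector = TRUE)
  list(series = series, label_map = label, truth_t2_map = t2,
       truth_beta_map = beta, masks = masks, spec = spec)
}

#' Rebuild a phantom spec from its JSON form
#'
#' @param x Path to a `spec.json` (or an already-parsed list).
#' @return A validated [phantom_spec()].
#' @export
phantom_spec_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  if (!is.null(x$tissue_params)) {
    fields <- c("t2_mean", "t2_sd", "beta_mean", "beta_sd")
    x$tissue_params <- lapply(x$tissue_params, function(p) {
      p <- as.list(p)  # JSON null (serialized NA) comes back as NULL
      vapply(fields, function(f) {
        v <- suppressWarnings(as.numeric(p[[f]]))  # "NA"/null -> NA
        if (!length(v)) NA_real_ else v
      }, numeric(1))
    })
  }
  if (!is.null(x$component_blobs) && is.data.frame(x$component_blobs))
    x$component_blobs <- lapply(seq_len(nrow(x$component_blobs)), function(i) {
      b <- x$component_blobs[i, ]
      list(tissue = b$tissue, center = unlist(b$center), radius_px = b$radius_px)
    })
  args <- x[names(x) %in% names(formals(phantom_spec))]
  do.call(phantom_spec, args)
}

#' Read a labelled training-voxel table
#'
#' Two delimited-text forms are accepted: `(class, t2_ms)` rows giving the
#' T2 value directly, or `(class, row, col)` rows giving 1-based voxel
#' coordinates that are resolved against a supplied T2 map (the voxel must
#' be accepted there). Invalid rows abort with their line numbers.
#'
#' @param path CSV file with a header.
#' @param t2_map A [fit_t2_map()] result, required for the coordinate
#'   form.
#' @return Tibble with columns `class` and `t2_ms`, ready for
#'   [train_class_model()].
#' @export
read_training_table <- function(path, t2_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!nrow(df)) abort("Training table is empty.")
  if (!"class" %in% names(df)) abort("Training table needs a `class` column.")
  if ("t2_ms" %in% names(df)) {
    bad <- which(!is.finite(df$t2_ms) | df$t2_ms <= 0)
    if (length(bad))
      abort(paste0("Non-positive t2_ms on line(s): ",
                   paste(bad + 1, collapse = ", ")))
    return(tibble(class = as.character(df$class), t2_ms = df$t2_ms))
  }
  if (!all(c("row", "col") %in% names(df)))
    abort("Training table needs either `t2_ms` or `row`+`col` columns.")
  if (is.null(t2_map))
    abort("Coordinate-form training tables need a `t2_map` to resolve against.")
  dims <- dim(t2_map$t2_ms)
  bad <- which(df$row < 1 | df$row > dims[1] | df$col < 1 | df$col > dims[2])
  if (length(bad))
    abort(paste0("Coordinates outside the grid on line(s): ",
                 paste(bad + 1, collapse = ", ")))
  t2 <- t2_map$t2_ms[cbind(df$row, df$col)]
  bad <- which(!is.finite(t2))
  if (length(bad))
    abort(paste0("Rejected/unfitted voxels on line(s): ",
                 paste(bad + 1, collapse = ", ")))
  tibble(class = as.character(df$class), t2_ms = t2)
}
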