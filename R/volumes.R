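#' Tissue-probability images and atlas parcellations
#'
#' A `tissue_image` holds one subject's 3-D tissue-probability map (gray
#' matter, white matter or CSF): voxel values in \[0, 1\] on a cubic lattice,
#' together with the subject id, tissue type, voxel size and class label.
#' An `atlas_parcellation` holds an integer label volume on the same grid
#' (0 = background) plus a region table mapping label ids to region names.
#' Both are thin S3 wrappers around plain 3-D arrays.
#'
#' @param data 3-D numeric array of tissue probabilities in \[0, 1\].
#' @param subject_id Subject identifier.
#' @param tissue One of `"GM"`, `"WM"`, `"CSF"`.
#' @param label Class label: `"NC"`, `"AD"`, `"MCI_C"` or `NA` (unlabeled).
#' @param voxel_size_mm Positive voxel edge lengths (length 1 or 3), in mm.
#' @param affine Optional 4x4 voxel-to-world matrix (used only to check that
#'   image and atlas share a grid).
#' @return An object of class `tissue_image`.
#' @export
tissue_image <- function(data, subject_id, tissue = c("GM", "WM", "CSF"),
                         label = NA, voxel_size_mm = 1.5, affine = NULL) {
  tissue <- match.arg(tissue)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("tissue data must be a 3-D array")
  }
  data <- validate_probability_volume(data, what = paste0("subject ", subject_id))
  structure(
    list(subject_id = as.character(subject_id), tissue = tissue,
         data = data, voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
         label = if (is.na(label)) NA_character_ else as.character(label),
         affine = affine),
    class = "tissue_image"
  )
}

#' @rdname tissue_image
#' @param labels 3-D array of non-negative integer region labels.
#' @param region_table Data frame with columns `region_id`, `region_name`;
#'   defaults to `region_<id>` names for every nonzero label present.
#' @export
atlas_parcellation <- function(labels, region_table = NULL,
                               voxel_size_mm = 1.5, affine = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("atlas labels must be a 3-D array")
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    abort("atlas labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.integer(labels[labels > 0L])))
  if (is.null(region_table)) {
    region_table <- tibble::tibble(region_id = ids,
                                   region_name = paste0("region_", ids))
  } else {
    region_table <- tibble::as_tibble(region_table)
    stopifnot(all(c("region_id", "region_name") %in% names(region_table)))
    region_table$region_id <- as.integer(region_table$region_id)
    missing <- setdiff(ids, region_table$region_id)
    if (length(missing) > 0L) {
      abort(paste0("atlas labels absent from region table: ",
                   paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(labels = labels, region_table = region_table,
         voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
         affine = affine),
    class = "atlas_parcellation"
  )
}

#' @export
print.tissue_image <- function(x, ...) {
  cat(sprintf("<tissue_image> subject %s, %s, grid %s, label %s\n",
              x$subject_id, x$tissue, paste(dim(x$data), collapse = "x"),
              x$label %||% "NA"))
  invisible(x)
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("<atlas_parcellation> grid %s, %d regions\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$region_table)))
  invisible(x)
}

# Probability volumes tolerate float round-off of 1e-6 outside [0,1];
# values beyond that are an input error, values inside are clipped.
validate_probability_volume <- function(data, what = "volume", tol = 1e-6) {
  rng <- range(data)
  if (rng[1] < -tol || rng[2] > 1 + tol) {
    abort(sprintf(
      "probability values outside [0, 1] in %s (range %.6g .. %.6g)",
      what, rng[1], rng[2]))
  }
  data[] <- pmin(pmax(data, 0), 1)
  data
}

#' Read a NIfTI volume as a tissue image or atlas
#'
#' Reads a NIfTI-1 file. For `kind = "tissue"` the voxel values are validated
#' to lie in \[-1e-6, 1 + 1e-6\] (and clipped to \[0, 1\]); for
#' `kind = "atlas"` they must be non-negative integers. Voxel size and affine
#' are taken from the header.
#'
#' @param path Path to a readable NIfTI file.
#' @param kind `"tissue"` (default) or `"atlas"`.
#' @inheritParams tissue_image
#' @inheritParams atlas_parcellation
#' @return A [tissue_image()] or [atlas_parcellation()].
#' @export
load_volume <- function(path, kind = c("tissue", "atlas"), subject_id = NA,
                        tissue = "GM", label = NA, region_table = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("cannot read NIfTI file: ", path))
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) dm <- dm[1:3]
  arr <- array(as.vector(img), dim = dm)
  vox <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  if (kind == "tissue") {
    arr <- tryCatch(validate_probability_volume(arr, what = path),
                    error = function(e) abort(conditionMessage(e)))
    tissue_image(arr, subject_id = subject_id, tissue = tissue, label = label,
                 voxel_size_mm = vox, affine = aff)
  } else {
    atlas_parcellation(arr, region_table = region_table,
                       voxel_size_mm = vox, affine = aff)
  }
}

#' Write a tissue image or atlas to NIfTI
#'
#' @param x A [tissue_image()] or [atlas_parcellation()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "tissue_image")) x$data else x$labels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_same_grid <- function(image, atlas, tol = 1e-4) {
  if (!identical(dim(image$data), dim(atlas$labels))) {
    abort(sprintf("grid mismatch: image %s vs atlas %s",
                  paste(dim(image$data), collapse = "x"),
                  paste(dim(atlas$labels), collapse = "x")))
  }
  if (!is.null(image$affine) && !is.null(atlas$affine) &&
      max(abs(image$affine - atlas$affine)) > tol) {
    abort("affine mismatch between image and atlas (no registration is performed)")
  }
  invisible(TRUE)
}

#' Extract per-region feature vectors from a tissue image
#'
#' `extract_component()` pulls the voxel probabilities of one atlas region
#' out of a subject's tissue image and concatenates them to a feature vector;
#' `decompose()` does so for a set of regions. The scan order is fixed for
#' all subjects: the voxel lattice is traversed with x varying fastest, then
#' y, then z (array column-major order), so identical `region_id` always
#' yields features of identical length S in identical voxel order.
#'
#' @param image A [tissue_image()].
#' @param atlas An [atlas_parcellation()] on the same grid.
#' @param region_id Integer region label present in the atlas.
#' @param region_ids Integer vector of region labels.
#' @return A tibble with one row per region: `subject_id`, `region_id`,
#'   `label`, `s` (voxel count) and a list-column `feature` holding the
#'   numeric vector.
#' @export
extract_component <- function(image, atlas, region_id) {
  decompose(image, atlas, region_ids = region_id)
}

#' @rdname extract_component
#' @export
decompose <- function(image, atlas, region_ids = atlas$region_table$region_id) {
  stopifnot(inherits(image, "tissue_image"), inherits(atlas, "atlas_parcellation"))
  check_same_grid(image, atlas)
  region_ids <- as.integer(region_ids)
  known <- atlas$region_table$region_id
  missing <- setdiff(region_ids, known)
  if (length(missing) > 0L) {
    abort(paste0("region id(s) not present in atlas: ",
                 paste(missing, collapse = ", ")))
  }
  feats <- lapply(region_ids, function(id) {
    image$data[which(atlas$labels == id)]
  })
  tibble::tibble(
    subject_id = image$subject_id,
    region_id = region_ids,
    label = image$label,
    s = lengths(feats),
    feature = feats
  )
}

#' Decompose a cohort of tissue images into component features
#'
#' Applies [decompose()] to every image and stacks the results, giving the
#' long feature table consumed by [loocv_outcomes()].
#'
#' @param images List of [tissue_image()] objects (one tissue per subject).
#' @inheritParams extract_component
#' @return Tibble with columns `subject_id`, `region_id`, `label`, `s`,
#'   `feature` (list-column).
#' @export
decompose_cohort <- function(images, atlas,
                             region_ids = atlas$region_table$region_id) {
  purrr::map(images, decompose, atlas = atlas, region_ids = region_ids) |>
    purrr::list_rbind()
}

#' Read a subject manifest
#'
#' The manifest CSV lists one subject per row with columns `subject_id`,
#' `gm_path`, `wm_path`, `csf_path` (paths may be empty) and
#' `label` in `{NC, AD, MCI_C}`.
#'
#' @param path Manifest CSV path.
#' @return A tibble with the manifest columns plus `y` (+1 AD, -1 NC,
#'   `NA` for MCI converters).
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("subject_id", "label") %in% names(m)))
  m$subject_id <- as.character(m$subject_id)
  m$y <- label_to_y(m$label)
  m
}
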