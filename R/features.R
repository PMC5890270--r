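#' Per-patch structural volume features
#'
#' The deformation transferring the template patches encodes local
#' expansion/contraction, so the subject-space volume of each template
#' patch measures regional brain structure. Volume of patch j is its
#' subject-space voxel count times the voxel volume (mm^3). Patches
#' emptied by the deformation get volume 0 and are flagged missing.
#'
#' @param subject_map a subject-space `patch_map` (see
#'   [transfer_patchmap()]).
#' @param spacing voxel spacing (mm); defaults to the map's own.
#' @param image_id identifier carried on the result.
#' @return A `patch_feature_vector`: list with `image_id`, `modality`
#'   (`"volume"`), `scale`, `values` (length P, mm^3) and `missing_mask`.
#' @export
patch_volumes <- function(subject_map, spacing = subject_map$labels$spacing,
                          image_id = "image") {
  stopifnot(inherits(subject_map, "patch_map"))
  voxel_mm3 <- prod(spacing)
  n_vox <- subject_map$patch_table$n_voxels
  patch_feature_vector(image_id, "volume", subject_map$scale,
                       values = n_vox * voxel_mm3,
                       missing_mask = n_vox == 0L,
                       patch_ids = subject_map$patch_table$patch_id)
}

patch_feature_vector <- function(image_id, modality, scale, values,
                                 missing_mask, patch_ids) {
  stopifnot(length(values) == length(missing_mask),
            length(values) == length(patch_ids))
  structure(list(image_id = image_id, modality = modality,
                 scale = as.integer(scale), values = as.numeric(values),
                 missing_mask = as.logical(missing_mask),
                 patch_ids = as.integer(patch_ids)),
            class = "patch_feature_vector")
}

#' Normalize a PET volume to its brainstem mean
#'
#' Divides every voxel by the mean intensity over the brainstem mask, the
#' reference region presumed unaffected by Alzheimer's disease, making
#' metabolism features comparable across subjects and invariant to global
#' scanner scaling. The mask mean of the output is exactly 1.
#'
#' @param pet an [intensity_volume()].
#' @param brainstem_mask a [label_volume()] on the same grid; any nonzero
#'   voxel belongs to the mask.
#' @return The normalized [intensity_volume()].
#' @export
normalize_to_brainstem <- function(pet, brainstem_mask) {
  stopifnot(inherits(pet, "intensity_volume"),
            inherits(brainstem_mask, "label_volume"))
  assert_same_grid(pet, brainstem_mask)
  inside <- brainstem_mask$data != 0L
  if (!any(inside)) stop("brainstem mask is empty")
  ref <- mean(pet$data[inside])
  if (!is.finite(ref) || abs(ref) < 1e-12)
    stop("brainstem reference mean is zero or near zero (", format(ref), ")")
  intensity_volume(pet$data / ref, pet$spacing, header = pet$header)
}

#' Per-patch mean metabolism features
#'
#' Mean normalized PET intensity over each patch's subject-space voxels.
#' Empty patches are flagged missing (NA value), never silently
#' zero-filled: zero metabolism is not a physically meaningful default.
#'
#' @param subject_map a subject-space `patch_map`.
#' @param pet_norm a brainstem-normalized [intensity_volume()] on the same
#'   grid.
#' @param image_id identifier carried on the result.
#' @return A `patch_feature_vector` with modality `"metabolism"`.
#' @export
patch_mean_intensities <- function(subject_map, pet_norm, image_id = "image") {
  stopifnot(inherits(subject_map, "patch_map"),
            inherits(pet_norm, "intensity_volume"))
  assert_same_grid(subject_map$labels, pet_norm)
  P <- nrow(subject_map$patch_table)
  lab <- as.vector(subject_map$labels$data)
  keep <- lab > 0L
  sums <- numeric(P)
  s <- rowsum(as.vector(pet_norm$data)[keep], lab[keep])
  sums[as.integer(rownames(s))] <- s[, 1]
  counts <- subject_map$patch_table$n_voxels
  values <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  patch_feature_vector(image_id, "metabolism", subject_map$scale,
                       values = values, missing_mask = counts == 0L,
                       patch_ids = subject_map$patch_table$patch_id)
}

#' Assemble per-image feature vectors into modality-by-scale matrices
#'
#' Collects one `patch_feature_vector` per (image, modality, scale) into
#' dense images x patches matrices, rows ordered exactly as `metadata`.
#' Missing entries are imputed — volume to 0 (a vanished patch has zero
#' volume), metabolism to the column mean over non-missing rows — and
#' every imputation is recorded in the `"imputation_log"` attribute.
#'
#' @param vectors list of `patch_feature_vector` objects covering every
#'   image in `metadata` for every (modality, scale) combination present.
#' @param metadata data.frame with at least `image_id`; row order defines
#'   matrix row order. Duplicate image ids are an error.
#' @return Named list of matrices, one per `"<modality>_<scale>"`, each
#'   with rownames `image_id` and colnames `patch_<id>`; identical row
#'   order across matrices.
#' @export
assemble_feature_matrices <- function(vectors, metadata) {
  stopifnot(is.data.frame(metadata), "image_id" %in% names(metadata))
  ids <- as.character(metadata$image_id)
  if (anyDuplicated(ids)) stop("duplicate image ids in metadata")
  keys <- vapply(vectors, function(v) paste0(v$modality, "_", v$scale), "")
  out <- list()
  log <- list()
  for (key in sort(unique(keys))) {
    vs <- vectors[keys == key]
    vids <- vapply(vs, function(v) as.character(v$image_id), "")
    if (anyDuplicated(vids)) stop("duplicate vectors for ", key)
    missing_imgs <- setdiff(ids, vids)
    if (length(missing_imgs))
      stop("images lacking a ", key, " vector: ",
           paste(utils::head(missing_imgs, 5), collapse = ", "))
    ord <- match(ids, vids)
    pids <- vs[[1]]$patch_ids
    mat <- t(vapply(vs[ord], function(v) {
      if (!identical(v$patch_ids, pids)) stop("inconsistent patch ids in ", key)
      v$values
    }, numeric(length(pids))))
    miss <- t(vapply(vs[ord], function(v) v$missing_mask, logical(length(pids))))
    modality <- vs[[1]]$modality
    if (any(miss)) {
      if (modality == "volume") {
        mat[miss] <- 0
      } else {
        col_means <- colMeans(ifelse(miss, NA, mat), na.rm = TRUE)
        col_means[!is.finite(col_means)] <- 0  # column missing everywhere
        mat[miss] <- col_means[col(mat)[miss]]
      }
      log[[key]] <- data.frame(image_id = ids[row(mat)[miss]],
                               patch_id = pids[col(mat)[miss]],
                               modality = modality)
    }
    dimnames(mat) <- list(ids, paste0("patch_", pids))
    out[[key]] <- mat
  }
  structure(out, imputation_log = log)
}

#' Standardize feature matrices with training statistics
#'
#' Centres and scales every column of `train` to mean 0, sd 1 (constant
#' columns map to all zeros), then applies the training statistics — and
#' only those — to any other matrices, as required to keep test data out
#' of the fitted transform.
#'
#' @param train numeric matrix (rows = images).
#' @param others optional list of matrices with the same columns.
#' @return list with `train`, `others`, `center` and `scale` (the
#'   population standard deviation used; constant columns recorded with
#'   scale 0 but transformed safely).
#' @export
standardize_features <- function(train, others = list()) {
  stopifnot(is.matrix(train), nrow(train) >= 1)
  center <- colMeans(train)
  scale <- sqrt(colMeans(sweep(train, 2, center, "-")^2))
  safe <- ifelse(scale > 0, scale, 1)
  transform <- function(m) {
    z <- sweep(sweep(m, 2, center, "-"), 2, safe, "/")
    z[, scale == 0] <- 0
    z
  }
  list(train = transform(train), others = lapply(others, transform),
       center = center, scale = scale)
}

#' Read and write feature matrices and cohort metadata as TSV
#'
#' Feature matrices are written one file per modality-by-scale
#' combination (`features_<modality>_<scale>.tsv`), rows = image ids.
#' Metadata TSV carries `subject_id`, `image_id`, `group`, `timepoint`,
#' `years_to_conversion`.
#'
#' @param features named list of feature matrices (see
#'   [assemble_feature_matrices()]).
#' @param dir output directory (created if needed).
#' @return `write_feature_matrices` returns `dir` invisibly;
#'   `read_feature_matrices` the named list of matrices.
#' @export
write_feature_matrices <- function(features, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (key in names(features)) {
    df <- data.frame(image_id = rownames(features[[key]]),
                     features[[key]], check.names = FALSE)
    write.table(df, file.path(dir, paste0("features_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_feature_matrices
#' @export
read_feature_matrices <- function(dir) {
  files <- list.files(dir, pattern = "^features_.*\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no features_*.tsv files in ", dir)
  out <- list()
  for (f in files) {
    key <- sub("^features_(.*)\\.tsv$", "\\1", basename(f))
    df <- read.delim(f, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$image_id
    out[[key]] <- m
  }
  out
}
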