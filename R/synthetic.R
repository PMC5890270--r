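#' Synthetic staged-cohort configuration
#'
#' Desk-scale stand-in for the clinical cohort structure: five diagnostic
#' groups (sNC, sMCI, pNC, pMCI, sAD), longitudinal images per subject,
#' and a latent disease stage in `[0, 1]` that drives regional volume
#' loss (`delta_vol`) and metabolism reduction (`delta_met`) on an
#' affected subset of regions, with multiplicative lognormal noise.
#' Stage is 0 for sNC, `stage_floor` for sMCI, 1 for sAD, and
#' `clamp(1 - years_to_conversion / max_years, stage_floor, 1)` for the
#' progressive groups; pNC subjects convert from farther out, so their
#' years-to-conversion are drawn from the upper half of the range and
#' pMCI from the lower half.
#'
#' The defaults are deliberately small — a 48^3 grid, 12 ROIs plus
#' brainstem, tens of patches per scale and tens of subjects per group —
#' so the whole pipeline (including ensembles of networks) runs on a
#' laptop core.
#'
#' @param grid_shape template grid (3 ints).
#' @param n_rois number of gray-matter ROIs (brainstem is added with
#'   label `brainstem_label`).
#' @param brainstem_label label id of the brainstem region.
#' @param patch_sizes nominal voxels-per-patch per scale.
#' @param patches_per_scale patch counts used by the fast feature path
#'   (bypasses volumes; keeps branch input dims in the tens).
#' @param group_sizes named vector of subjects per group.
#' @param images_per_subject inclusive (min, max) range of longitudinal
#'   images per subject, one year apart.
#' @param years_to_conversion_range (min, max) years before conversion
#'   at baseline for progressive subjects.
#' @param affected_fraction fraction of ROIs/patches carrying disease
#'   effect.
#' @param delta_vol,delta_met maximal fractional volume loss and
#'   metabolism reduction at stage 1 (each in `[0, 1)`).
#' @param sigma_vol,sigma_met lognormal (log-scale) noise SDs.
#' @param stage_floor minimal nonzero stage (sMCI level).
#' @param jitter_mm amplitude of the smooth random deformation jitter.
#' @param complementary if TRUE the fast path places volume and
#'   metabolism effects on disjoint patch sets (used to probe multimodal
#'   fusion gain); default FALSE colocalizes them.
#' @param seed integer seed; all outputs deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(48, 48, 48), n_rois = 12L,
                       brainstem_label = n_rois + 1L,
                       patch_sizes = c(40, 80, 160),
                       patches_per_scale = c(32, 16, 8),
                       group_sizes = c(sNC = 30, sMCI = 30, pNC = 12,
                                       pMCI = 30, sAD = 30),
                       images_per_subject = c(1, 2),
                       years_to_conversion_range = c(0.5, 8),
                       affected_fraction = 0.4,
                       delta_vol = 0.3, delta_met = 0.3,
                       sigma_vol = 0.05, sigma_met = 0.05,
                       stage_floor = 0.1, jitter_mm = 0.15,
                       complementary = FALSE, seed = 1L) {
  known <- c("sNC", "sMCI", "pNC", "pMCI", "sAD")
  if (!all(names(group_sizes) %in% known))
    stop("group names must be among: ", paste(known, collapse = ", "))
  if (delta_vol < 0 || delta_vol >= 1 || delta_met < 0 || delta_met >= 1)
    stop("effect sizes must be in [0, 1)")
  if (length(images_per_subject) == 1)
    images_per_subject <- rep(images_per_subject, 2)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_rois = as.integer(n_rois),
                 brainstem_label = as.integer(brainstem_label),
                 patch_sizes = as.integer(patch_sizes),
                 patches_per_scale = as.integer(patches_per_scale),
                 group_sizes = group_sizes,
                 images_per_subject = as.integer(images_per_subject),
                 years_to_conversion_range = as.numeric(years_to_conversion_range),
                 affected_fraction = affected_fraction,
                 delta_vol = delta_vol, delta_met = delta_met,
                 sigma_vol = sigma_vol, sigma_met = sigma_met,
                 stage_floor = stage_floor, jitter_mm = jitter_mm,
                 complementary = isTRUE(complementary),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic template label volume
#'
#' Packs `n_rois` rectangular ROIs plus a brainstem region on a lattice
#' of cells with generous background margins (so that per-ROI
#' contractions stay resolvable), labelled 1..n_rois and
#' `brainstem_label`. Per-ROI baselines and the affected-ROI subset are
#' attached as attributes for the volume simulator. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A [label_volume()] with attributes `affected_rois` and
#'   `roi_baselines` (mean PET baseline per label).
#' @export
make_template_labels <- function(cfg) {
  set.seed(cfg$seed)
  shape <- cfg$grid_shape
  n_regions <- cfg$n_rois + 1L
  # smallest near-cubic lattice holding all regions
  slots <- c(1L, 1L, 1L)
  while (prod(slots) < n_regions) {
    i <- which.min(slots * shape / max(shape))  # grow the relatively smallest
    slots[i] <- slots[i] + 1L
  }
  cell <- floor(shape / slots)
  if (any(cell < 6)) stop("grid too small to pack ", n_regions, " ROIs")
  labels <- array(0L, shape)
  slot_order <- sample(prod(slots))[seq_len(n_regions)]
  region_labels <- c(seq_len(cfg$n_rois), cfg$brainstem_label)
  for (r in seq_len(n_regions)) {
    s0 <- slot_order[r] - 1L
    si <- c(s0 %% slots[1], (s0 %/% slots[1]) %% slots[2],
            s0 %/% (slots[1] * slots[2]))
    half <- pmax(1L, as.integer(floor(cell * runif(3, 0.2, 0.3))))
    centre <- as.integer(si * cell + floor(cell / 2)) + 1L
    lo <- pmax(centre - half, 1L)
    hi <- pmin(centre + half, shape)
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- region_labels[r]
  }
  vol <- label_volume(labels, spacing = c(1, 1, 1))
  n_aff <- max(1L, round(cfg$affected_fraction * cfg$n_rois))
  attr(vol, "affected_rois") <- sort(sample(cfg$n_rois, n_aff))
  baselines <- runif(n_regions, 0.8, 1.2)
  baselines[n_regions] <- 1.3  # brainstem reference, never modulated
  attr(vol, "roi_baselines") <- setNames(baselines, region_labels)
  vol
}

stage_of <- function(group, years, cfg) {
  tau <- cfg$years_to_conversion_range[2]
  ifelse(group == "sNC", 0,
    ifelse(group == "sMCI", cfg$stage_floor,
      ifelse(group == "sAD", 1,
        pmin(pmax(1 - years / tau, cfg$stage_floor), 1))))
}

#' Synthetic cohort metadata
#'
#' One row per image: `subject_id`, `image_id`, `group`, `timepoint`
#' (years from baseline, images one year apart) and
#' `years_to_conversion` (progressive groups; 0 for sAD, NA for stable
#' groups, floored at 0 for post-conversion timepoints). Baseline
#' years-to-conversion are uniform in the upper half of the configured
#' range for pNC and the lower half for pMCI.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed override (default `cfg$seed`).
#' @return A data.frame of cohort metadata.
#' @export
make_cohort_metadata <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  rng <- cfg$years_to_conversion_range
  mid <- mean(rng)
  rows <- list()
  s <- 0L
  for (g in names(cfg$group_sizes)) {
    for (k in seq_len(cfg$group_sizes[[g]])) {
      s <- s + 1L
      sid <- sprintf("S%04d", s)
      rng_img <- cfg$images_per_subject
      n_img <- if (rng_img[1] == rng_img[2]) rng_img[1] else
        sample(rng_img[1]:rng_img[2], 1)
      y0 <- switch(g,
                   pNC = runif(1, mid, rng[2]),
                   pMCI = runif(1, rng[1], mid),
                   NA_real_)
      tps <- seq_len(n_img) - 1L
      years <- switch(g,
                      pNC = pmax(y0 - tps, 0),
                      pMCI = pmax(y0 - tps, 0),
                      sAD = rep(0, n_img),
                      rep(NA_real_, n_img))
      rows[[s]] <- data.frame(subject_id = sid,
                              image_id = sprintf("%s_T%d", sid, tps),
                              group = g, timepoint = tps,
                              years_to_conversion = years)
    }
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  md
}

#' Simulate one subject's deformation field and PET volume
#'
#' The displacement field contracts every affected ROI about its centroid
#' by `1 - delta_vol * stage` per axis (pull-back convention: the
#' transferred ROI occupies roughly that factor cubed of its template
#' volume) plus a smooth sinusoidal jitter. The PET volume holds each
#' region's baseline intensity, reduced by `delta_met * stage` in
#' affected ROIs, under voxelwise lognormal noise; the brainstem
#' intensity distribution is identical across groups.
#'
#' @param template a template from [make_template_labels()] (carries the
#'   affected-ROI set and baselines as attributes).
#' @param group diagnostic group of the subject.
#' @param stage disease stage in `[0, 1]`, consistent with the group.
#' @param cfg a [sim_config()].
#' @param seed per-subject RNG seed.
#' @return list with `field` (a [displacement_field()] on the template
#'   grid), `pet` (an [intensity_volume()]) and `labels` (the
#'   subject-space ROI [label_volume()]).
#' @export
simulate_subject_volumes <- function(template, group, stage, cfg,
                                     seed = cfg$seed) {
  stopifnot(inherits(template, "label_volume"), stage >= 0, stage <= 1)
  set.seed(seed)
  shape <- grid_shape(template)
  spacing <- template$spacing
  affected <- attr(template, "affected_rois")
  baselines <- attr(template, "roi_baselines")
  n <- prod(shape)
  field <- array(0, c(shape, 3L))
  contraction <- 1 - cfg$delta_vol * stage
  for (r in affected) {
    idx <- which(template$data == r)
    if (!length(idx)) next
    coords <- voxel_coords(idx, shape, spacing)
    # dither the contraction centre by up to a few voxels: inter-subject
    # anatomical variability, and it spreads the scaled coordinate lattice
    # over a full voxel phase so nearest-neighbour counts are unbiased
    # across subjects rather than locked to one rounding regime
    centroid <- colMeans(coords) + runif(3, -2.5, 2.5) * spacing
    factor <- 1 / contraction - 1
    for (comp in 1:3)
      field[idx + (comp - 1L) * n] <- (coords[, comp] - centroid[comp]) * factor
  }
  if (cfg$jitter_mm > 0) {
    phases <- runif(3, 0, 2 * pi)
    freq <- runif(3, 0.5, 1.5)
    i <- rep_len(seq_len(shape[1]) - 1L, n)
    j <- rep(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3])
    k <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
    extent <- (shape - 1) * spacing
    for (comp in 1:3) {
      pos <- switch(comp, i * spacing[1], j * spacing[2], k * spacing[3])
      field[(comp - 1L) * n + seq_len(n)] <-
        field[(comp - 1L) * n + seq_len(n)] +
        cfg$jitter_mm * sin(2 * pi * freq[comp] * pos / extent[comp] +
                            phases[comp])
    }
  }
  dfield <- displacement_field(field, spacing)

  roi_map <- roi_patchmap(template)
  subj_map <- transfer_patchmap(roi_map, dfield,
                                list(shape = shape, spacing = spacing))
  lab <- subj_map$labels$data
  intensity <- array(0, shape)
  inside <- lab > 0L
  base <- baselines[as.character(lab[inside])]
  mod <- ifelse(lab[inside] %in% affected, 1 - cfg$delta_met * stage, 1)
  intensity[inside] <- base * mod * exp(rnorm(sum(inside), 0, cfg$sigma_met))
  list(field = dfield,
       pet = intensity_volume(intensity, spacing),
       labels = subj_map$labels)
}

# View the ROI segmentation itself as a one-patch-per-ROI patch map
# (labels are already contiguous 1..n_regions in synthetic templates).
roi_patchmap <- function(template) {
  ids <- sort(setdiff(unique(as.vector(template$data)), 0L))
  if (!identical(ids, seq_along(ids)))
    stop("ROI labels must be contiguous 1..R for roi_patchmap")
  structure(list(labels = template,
                 patch_table = data.frame(patch_id = ids, roi_id = ids,
                                          n_voxels = tabulate(template$data[template$data > 0L],
                                                              nbins = length(ids)),
                                          scale = NA_integer_),
                 scale = NA_integer_),
            class = "patch_map")
}

#' Simulate feature tables with known effect structure
#'
#' Fast path bypassing volumes: draws the six modality-by-scale feature
#' matrices directly from the generative model
#' `vol_ij = mu_j * (1 - delta_vol * stage_i * a_j) * exp(eps_ij)` (and
#' the metabolism analogue with indicator `b_j`), with
#' `eps ~ Normal(0, sigma^2)`, patch baselines `mu_j` uniform around the
#' nominal patch volume (volume, mm^3) or around 1 (normalized
#' metabolism). By default the affected sets `a` and `b` coincide
#' (colocalized pathology); with `cfg$complementary` they are disjoint.
#'
#' @param cfg a [sim_config()].
#' @return list with `features` (named list of six matrices, rows aligned
#'   with `metadata`), `metadata`, and `truth` (per-scale affected-patch
#'   indicators for each modality, plus per-image `stages`).
#' @export
simulate_feature_tables <- function(cfg) {
  metadata <- make_cohort_metadata(cfg)  # seeds with cfg$seed
  stages <- stage_of(metadata$group, metadata$years_to_conversion, cfg)
  n <- nrow(metadata)
  features <- list()
  affected_vol <- list()
  affected_met <- list()
  for (s in seq_along(cfg$patch_sizes)) {
    P <- cfg$patches_per_scale[s]
    size <- cfg$patch_sizes[s]
    n_aff <- max(1L, round(cfg$affected_fraction * P))
    a <- sort(sample(P, n_aff))
    b <- if (cfg$complementary) sort(sample(setdiff(seq_len(P), a),
                                            min(n_aff, P - n_aff))) else a
    mu_vol <- runif(P, 0.8, 1.2) * size
    mu_met <- runif(P, 0.9, 1.1)
    a_ind <- as.numeric(seq_len(P) %in% a)
    b_ind <- as.numeric(seq_len(P) %in% b)
    vol <- outer(stages, a_ind, function(st, aj) 1 - cfg$delta_vol * st * aj)
    vol <- sweep(vol, 2, mu_vol, "*") *
      exp(matrix(rnorm(n * P, 0, cfg$sigma_vol), n, P))
    met <- outer(stages, b_ind, function(st, bj) 1 - cfg$delta_met * st * bj)
    met <- sweep(met, 2, mu_met, "*") *
      exp(matrix(rnorm(n * P, 0, cfg$sigma_met), n, P))
    dimnames(vol) <- dimnames(met) <-
      list(metadata$image_id, paste0("patch_", seq_len(P)))
    features[[paste0("volume_", size)]] <- vol
    features[[paste0("metabolism_", size)]] <- met
    affected_vol[[paste0("scale_", size)]] <- a
    affected_met[[paste0("scale_", size)]] <- b
  }
  list(features = features, metadata = metadata,
       truth = list(affected_volume = affected_vol,
                    affected_metabolism = affected_met,
                    stages = stages))
}

#' Read and write cohort metadata TSV
#'
#' @param metadata a cohort metadata data.frame.
#' @param path TSV file path.
#' @return `write_cohort_metadata` returns `path` invisibly;
#'   `read_cohort_metadata` the data.frame.
#' @export
write_cohort_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_metadata
#' @export
read_cohort_metadata <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
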