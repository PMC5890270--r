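# Shared fixtures: everything is generated in code at test time.

# Small label volume with two separated cuboid ROIs (labels 1, 2) and a
# brainstem block (label 3) on an isotropic grid.
block_template <- function(shape = c(20, 20, 20), spacing = c(1, 1, 1)) {
  arr <- array(0L, shape)
  arr[3:8, 3:8, 3:8] <- 1L        # 216 voxels
  arr[12:17, 3:8, 3:8] <- 2L      # 216 voxels
  arr[8:13, 12:17, 12:17] <- 3L   # brainstem
  label_volume(arr, spacing)
}

identity_field <- function(shape, spacing = c(1, 1, 1)) {
  displacement_field(array(0, c(shape, 3)), spacing)
}

# Uniform per-axis contraction about the grid origin: subject coordinate
# x maps to template coordinate x / factor (pull-back), so transferred
# structures shrink by factor^3 in volume. A sub-voxel offset keeps the
# mapped coordinates away from exact half-voxel rounding ties, which would
# otherwise bias nearest-neighbour counts systematically.
contraction_field <- function(shape, factor, spacing = c(1, 1, 1),
                              offset = c(0.13, 0.29, 0.71)) {
  n <- prod(shape)
  i <- rep_len(seq_len(shape[1]) - 1L, n)
  j <- rep(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3])
  k <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
  arr <- array(0, c(shape, 3))
  arr[, , , 1] <- array(i * spacing[1] * (1 / factor - 1) + offset[1], shape)
  arr[, , , 2] <- array(j * spacing[2] * (1 / factor - 1) + offset[2], shape)
  arr[, , , 3] <- array(k * spacing[3] * (1 / factor - 1) + offset[3], shape)
  displacement_field(arr, spacing)
}

# Single spherical ROI: large and round enough that nearest-neighbour
# boundary errors largely cancel in aggregate counts.
sphere_template <- function(shape = c(44, 44, 44), r = 9) {
  ctr <- (shape + 1) / 2
  n <- prod(shape)
  i <- rep_len(seq_len(shape[1]), n)
  j <- rep(rep(seq_len(shape[2]), each = shape[1]), shape[3])
  k <- rep(seq_len(shape[3]), each = shape[1] * shape[2])
  arr <- array(as.integer(((i - ctr[1])^2 + (j - ctr[2])^2 +
                             (k - ctr[3])^2) <= r^2), shape)
  label_volume(arr)
}

# Independent nearest-neighbour label-count oracle for a displacement
# field: recomputes, voxel by voxel, which template patch each subject
# voxel maps to (same pull-back + rounding convention, different code
# path from transfer_patchmap's vectorized lookup).
nn_transfer_counts <- function(template_map, field, shape, spacing = c(1, 1, 1)) {
  P <- nrow(template_map$patch_table)
  counts <- integer(P)
  tdim <- dim(template_map$labels$data)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      tc <- c((i - 1) * spacing[1] + field$data[i, j, k, 1],
              (j - 1) * spacing[2] + field$data[i, j, k, 2],
              (k - 1) * spacing[3] + field$data[i, j, k, 3])
      ti <- floor(tc / template_map$labels$spacing + 0.5) + 1
      if (all(ti >= 1) && all(ti <= tdim)) {
        lab <- template_map$labels$data[ti[1], ti[2], ti[3]]
        if (lab > 0) counts[lab] <- counts[lab] + 1L
      }
    }
  counts
}

# Exhaustive-partition oracle: minimal within-cluster SSE over all
# assignments of n points into at most k groups.
brute_force_sse <- function(coords, k) {
  n <- nrow(coords)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    s <- 0
    for (j in unique(a)) {
      pts <- coords[a == j, , drop = FALSE]
      s <- s + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    if (s < best) best <- s
  }
  best
}

# Central finite differences of a scalar function of one tensor.
numeric_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-8)
}

# Desk-scale training configuration used by experiment-level tests: the
# higher learning rate and tighter epoch budget match the small sample
# and batch counts of the synthetic cohorts.
desk_cfg <- function(seed = 1L) {
  train_config(learning_rate = 1e-3, pretrain_epochs = 6, head_epochs = 8,
               max_epochs = 25, patience = 7, seed = seed)
}

# Minimal config for structural unit tests where only mechanics matter.
tiny_cfg <- function(seed = 1L) {
  train_config(learning_rate = 1e-3, pretrain_epochs = 2, head_epochs = 2,
               max_epochs = 4, patience = 2, batch_size = 16, seed = seed)
}

# Reduced synthetic cohort for structural tests.
small_sim_cfg <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(group_sizes = c(sNC = 8, sMCI = 8, pNC = 4, pMCI = 8,
                                   sAD = 8),
                   patches_per_scale = c(10, 6, 4),
                   images_per_subject = c(1, 2), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Feature subset for the stable-vs-progressive MCI task (one image per
# subject via the selection rule).
mci_task_data <- function(sim) {
  sel <- mmdnn:::select_mci_images(sim$metadata)
  rows <- match(sel$image_id, sim$metadata$image_id)
  list(features = lapply(sim$features, function(f) f[rows, , drop = FALSE]),
       metadata = sim$metadata[rows, ],
       labels = as.integer(sim$metadata$group[rows] == "pMCI"))
}
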