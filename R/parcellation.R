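#' Parcellation scheme
#'
#' Bundles the tunables of the multiscale patch parcellation. Patch sizes
#' are nominal voxels-per-patch; the template defaults mirror the method's
#' 500/1000/2000-voxel hierarchy. k-means runs `n_restarts` seeded
#' restarts of Lloyd's algorithm with farthest-point initialization and
#' keeps the lowest within-cluster sum of squares (SSE).
#'
#' @param patch_sizes strictly increasing positive integers, nominal
#'   voxels per patch at each scale.
#' @param seed integer RNG seed controlling restarts.
#' @param n_restarts number of k-means restarts (>= 1).
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol convergence tolerance on centroid movement, mm.
#' @return A `parcellation_scheme` list.
#' @export
parcellation_scheme <- function(patch_sizes = c(500, 1000, 2000), seed = 1L,
                                n_restarts = 10L, max_iter = 300L, tol = 1e-6) {
  patch_sizes <- as.integer(patch_sizes)
  if (any(patch_sizes < 1)) stop("patch_sizes must be positive")
  if (is.unsorted(patch_sizes, strictly = TRUE))
    stop("patch_sizes must be strictly increasing")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (tol < 0) stop("tol must be non-negative")
  structure(list(patch_sizes = patch_sizes, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "parcellation_scheme")
}

#' Number of patches for an ROI
#'
#' Keeps the patch size density (patches in ROI / voxels in ROI) uniform
#' across regions: `k = max(1, round_half_up(n_roi_voxels / patch_size))`,
#' so every ROI keeps at least one patch however small it is.
#'
#' @param n_roi_voxels number of voxels in the ROI (>= 1).
#' @param patch_size nominal voxels per patch (>= 1).
#' @return A positive integer patch count.
#' @examples
#' patch_count(1000, 500)  # 2
#' patch_count(100, 500)   # 1
#' patch_count(1250, 500)  # 3 (half rounds up)
#' @export
patch_count <- function(n_roi_voxels, patch_size) {
  if (any(n_roi_voxels < 1) || any(patch_size < 1))
    stop("n_roi_voxels and patch_size must be >= 1")
  pmax(1L, as.integer(floor(n_roi_voxels / patch_size + 0.5)))
}

#' Spatial k-means over voxel coordinates
#'
#' Lloyd's algorithm on physical (mm) coordinates with deterministic
#' farthest-point seeding: the first centroid of each restart is a
#' uniformly drawn point, the remaining ones greedily maximize the minimum
#' distance to those already chosen (ties to the lowest point index).
#' Points are assigned to the nearest centroid with ties broken towards
#' the lowest cluster id; a cluster emptied during an update is reseeded
#' from the point farthest from its current centroid. The best of
#' `scheme$n_restarts` restarts by final SSE is returned.
#'
#' @param coords n x 3 numeric matrix of point coordinates (mm).
#' @param k number of clusters, `1 <= k <= nrow(coords)`.
#' @param scheme a [parcellation_scheme()]; its `seed` is NOT applied
#'   here — seed the session RNG (or rely on the caller) so nested use
#'   inside [build_template_patchmap()] stays deterministic.
#' @return list with `assignments` (length-n integer cluster ids 1..k),
#'   `centroids` (k x 3), `sse` (total within-cluster sum of squared
#'   distances) and `sse_trace` (assignment-step SSE per Lloyd iteration
#'   of the winning restart; non-increasing).
#' @export
kmeans_cluster_voxels <- function(coords, k, scheme = parcellation_scheme()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= number of points, got k = ",
                           k, " with ", n, " points")
  n_distinct <- nrow(unique(coords))
  if (n_distinct < k)
    stop("only ", n_distinct, " distinct points; cannot fill k = ", k, " clusters")

  best <- NULL
  for (r in seq_len(scheme$n_restarts)) {
    fit <- lloyd_once(coords, k, scheme$max_iter, scheme$tol,
                      greedy_seed = (r == 1L))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  best
}

lloyd_once <- function(coords, k, max_iter, tol, greedy_seed = FALSE) {
  n <- nrow(coords)
  # k-means++-style seeding from a random first pick: the first restart
  # picks each next centre greedily at the farthest point, later restarts
  # sample proportional to squared distance so restarts explore distinct
  # starts.
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k > 1) {
    d_min <- pmax(sq_dist_to(coords, coords[centers[1], , drop = FALSE])[, 1], 0)
    for (j in 2:k) {
      if (greedy_seed || sum(d_min) <= 0) {
        centers[j] <- which.max(d_min)  # ties -> lowest index
      } else {
        centers[j] <- sample.int(n, 1L, prob = d_min)
      }
      d_min <- pmax(pmin(d_min, sq_dist_to(coords, coords[centers[j], , drop = FALSE])[, 1]), 0)
    }
  }
  centroids <- coords[centers, , drop = FALSE]

  assign_prev <- integer(n)
  sse_trace <- numeric(0)
  for (outer in 1:20) {
    # Lloyd iterations to a fixed point
    for (it in seq_len(max_iter)) {
      D <- sq_dist_to(coords, centroids)
      assignment <- max.col(-D, ties.method = "first")
      sse_trace <- c(sse_trace, sum(D[cbind(seq_len(n), assignment)]))
      new_centroids <- centroids
      counts <- tabulate(assignment, nbins = k)
      while (any(counts == 0L)) {
        # reseed each empty cluster from the farthest point in a cluster
        # that can spare one
        j <- which(counts == 0L)[1]
        dist_own <- D[cbind(seq_len(n), assignment)]
        dist_own[counts[assignment] < 2L] <- -Inf
        far <- which.max(dist_own)
        assignment[far] <- j
        counts <- tabulate(assignment, nbins = k)
      }
      for (j in seq_len(k))
        new_centroids[j, ] <- colMeans(coords[assignment == j, , drop = FALSE])
      moved <- sqrt(max(rowSums((new_centroids - centroids)^2)))
      centroids <- new_centroids
      if (identical(assignment, assign_prev) || moved < tol) break
      assign_prev <- assignment
    }
    # Hartigan-style first-improvement moves escape Lloyd-stable local
    # minima (exact SSE delta for moving one point between clusters);
    # afterwards another Lloyd pass restores the fixed-point property.
    # Worth its O(n*k) per move only on small problems, where Lloyd local
    # minima actually bite; large spatial clusterings skip it.
    if (n > 512L || outer >= 5L) break
    res <- hartigan_moves(coords, assignment, centroids, k)
    if (!res$improved) break
    assignment <- res$assignment
    centroids <- res$centroids
    assign_prev <- integer(n)
  }
  D <- sq_dist_to(coords, centroids)
  assignment <- max.col(-D, ties.method = "first")
  list(assignments = assignment, centroids = centroids,
       sse = sum(D[cbind(seq_len(nrow(coords)), assignment)]),
       sse_trace = sse_trace)
}

hartigan_moves <- function(coords, assignment, centroids, k,
                           max_moves = 200L) {
  n <- nrow(coords)
  counts <- tabulate(assignment, nbins = k)
  improved_any <- FALSE
  for (mv in seq_len(max_moves)) {
    D <- pmax(sq_dist_to(coords, centroids), 0)
    na <- counts[assignment]
    gain_out <- ifelse(na > 1L, na / (na - 1L), 0) *
      D[cbind(seq_len(n), assignment)]
    cost_in <- sweep(D, 2, counts / (counts + 1L), "*")
    delta <- cost_in - gain_out           # n x k; delta to move i -> j
    delta[na == 1L, ] <- Inf              # never empty a cluster
    delta[cbind(seq_len(n), assignment)] <- Inf  # staying put is not a move
    best <- which.min(delta)
    if (delta[best] >= -1e-12) break
    i <- (best - 1L) %% n + 1L
    b <- (best - 1L) %/% n + 1L
    a <- assignment[i]
    centroids[a, ] <- (centroids[a, ] * counts[a] - coords[i, ]) / (counts[a] - 1L)
    centroids[b, ] <- (centroids[b, ] * counts[b] + coords[i, ]) / (counts[b] + 1L)
    counts[a] <- counts[a] - 1L
    counts[b] <- counts[b] + 1L
    assignment[i] <- b
    improved_any <- TRUE
  }
  list(improved = improved_any, assignment = assignment,
       centroids = centroids)
}

sq_dist_to <- function(coords, centroids) {
  # n x k matrix of squared Euclidean distances
  cross <- coords %*% t(centroids)
  sweep(-2 * cross, 2, rowSums(centroids^2), "+") + rowSums(coords^2)
}

#' Build the multiscale patch map of a template
#'
#' Subdivides every ROI of a template label volume into
#' [patch_count()] spatial k-means clusters of its voxel coordinates
#' (physical mm), then renumbers patches globally 1..P. Patches partition
#' the ROI voxels exactly and never straddle ROIs.
#'
#' @param template a [label_volume()] with at least one nonzero label.
#' @param scheme a [parcellation_scheme()]; `scheme$seed` makes the map
#'   deterministic.
#' @param patch_size nominal voxels per patch for this scale.
#' @return A `patch_map`: list with `labels` (a [label_volume()] of patch
#'   ids), `patch_table` (data.frame `patch_id`, `roi_id`, `n_voxels`,
#'   `scale`) and `scale`.
#' @export
build_template_patchmap <- function(template, scheme = parcellation_scheme(),
                                    patch_size = 500) {
  stopifnot(inherits(template, "label_volume"))
  roi_ids <- sort(setdiff(unique(as.vector(template$data)), 0L))
  if (length(roi_ids) == 0) stop("template has no nonzero labels")
  set.seed(scheme$seed)
  shape <- grid_shape(template)
  labels <- array(0L, shape)
  rows <- vector("list", length(roi_ids))
  next_id <- 1L
  for (i in seq_along(roi_ids)) {
    roi <- roi_ids[i]
    idx <- which(template$data == roi)
    coords <- voxel_coords(idx, shape, template$spacing)
    k <- patch_count(length(idx), patch_size)
    if (k == 1L) {
      assignment <- rep(1L, length(idx))
    } else {
      assignment <- kmeans_cluster_voxels(coords, k, scheme)$assignments
    }
    labels[idx] <- next_id - 1L + assignment
    rows[[i]] <- data.frame(patch_id = next_id:(next_id + k - 1L),
                            roi_id = roi,
                            n_voxels = tabulate(assignment, nbins = k),
                            scale = patch_size)
    next_id <- next_id + k
  }
  patch_table <- do.call(rbind, rows)
  rownames(patch_table) <- NULL
  structure(list(labels = label_volume(labels, template$spacing,
                                       header = template$header),
                 patch_table = patch_table, scale = as.integer(patch_size)),
            class = "patch_map")
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf("<patch_map> %d patches over %d ROIs, scale %d voxels/patch\n",
              nrow(x$patch_table), length(unique(x$patch_table$roi_id)), x$scale))
  invisible(x)
}

voxel_coords <- function(idx, shape, spacing) {
  idx0 <- idx - 1L
  i <- idx0 %% shape[1]
  j <- (idx0 %/% shape[1]) %% shape[2]
  k <- idx0 %/% (shape[1] * shape[2])
  cbind(i * spacing[1], j * spacing[2], k * spacing[3])
}

#' Transfer a template patch map to subject space
#'
#' Pulls patch labels through a displacement field: each subject voxel
#' centre plus its displacement gives a template coordinate, which is
#' looked up by nearest-neighbour (labels stay categorical); coordinates
#' falling outside the template grid map to background. Patch identity and
#' ROI assignment are preserved; subject-space voxel counts are
#' recomputed, and patches emptied by the deformation stay in the table
#' with `n_voxels = 0` (listed in the `"empty_patches"` attribute for
#' downstream imputation).
#'
#' @param template_map a `patch_map` from [build_template_patchmap()].
#' @param field a [displacement_field()] on the subject grid (pull-back
#'   convention, mm).
#' @param subject_grid the subject grid: either a volumetric container or
#'   a list with `shape` (3 ints) and `spacing` (3 mm values).
#' @return A subject-space `patch_map`.
#' @export
transfer_patchmap <- function(template_map, field, subject_grid) {
  stopifnot(inherits(template_map, "patch_map"),
            inherits(field, "displacement_field"))
  if (inherits(subject_grid, "brain_volume"))
    subject_grid <- list(shape = grid_shape(subject_grid),
                         spacing = subject_grid$spacing)
  shape <- as.integer(subject_grid$shape)
  spacing <- as.numeric(subject_grid$spacing)
  if (!identical(as.integer(dim(field$data)[1:3]), shape) ||
      max(abs(field$spacing - spacing)) > 1e-6)
    stop("grid mismatch: displacement field is not defined on subject_grid")

  n <- prod(shape)
  i <- rep_len(seq_len(shape[1]) - 1L, n)
  j <- rep(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3])
  k <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
  tx <- i * spacing[1] + as.vector(field$data[, , , 1])
  ty <- j * spacing[2] + as.vector(field$data[, , , 2])
  tz <- k * spacing[3] + as.vector(field$data[, , , 3])

  tmpl <- template_map$labels
  tshape <- grid_shape(tmpl)
  # nearest neighbour with half-up ties: half-even rounding would push
  # both boundary ties of a symmetrically scaled region outward and bias
  # transferred counts low
  ti <- as.integer(floor(tx / tmpl$spacing[1] + 0.5))
  tj <- as.integer(floor(ty / tmpl$spacing[2] + 0.5))
  tk <- as.integer(floor(tz / tmpl$spacing[3] + 0.5))
  ok <- ti >= 0L & ti < tshape[1] & tj >= 0L & tj < tshape[2] &
    tk >= 0L & tk < tshape[3]
  lab <- integer(n)
  lin <- ti[ok] + tshape[1] * (tj[ok] + tshape[2] * tk[ok]) + 1L
  lab[ok] <- tmpl$data[lin]

  patch_table <- template_map$patch_table
  patch_table$n_voxels <- tabulate(lab[lab > 0L], nbins = nrow(patch_table))
  out <- structure(list(labels = label_volume(array(lab, shape), spacing),
                        patch_table = patch_table,
                        scale = template_map$scale),
                   class = "patch_map")
  attr(out, "empty_patches") <- patch_table$patch_id[patch_table$n_voxels == 0L]
  out
}

#' Read and write patch maps
#'
#' A patch map is stored as a NIfTI label volume `<prefix>.nii.gz` plus a
#' sidecar TSV `<prefix>_patch_table.tsv` with columns `patch_id`,
#' `roi_id`, `n_voxels`, `scale`.
#'
#' @param map a `patch_map`.
#' @param prefix path prefix (without extension).
#' @return `write_patchmap` returns `prefix` invisibly; `read_patchmap`
#'   returns the `patch_map`.
#' @export
write_patchmap <- function(map, prefix) {
  stopifnot(inherits(map, "patch_map"))
  save_volume(map$labels, paste0(prefix, ".nii.gz"))
  write.table(map$patch_table, paste0(prefix, "_patch_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_patchmap
#' @export
read_patchmap <- function(prefix) {
  labels <- load_volume(paste0(prefix, ".nii.gz"), kind = "label")
  tab <- read.delim(paste0(prefix, "_patch_table.tsv"))
  structure(list(labels = labels, patch_table = tab,
                 scale = as.integer(tab$scale[1])),
            class = "patch_map")
}
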