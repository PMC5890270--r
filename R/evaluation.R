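#' Subject-level cross-validation folds
#'
#' Allocation into folds is done on the level of subjects, not images:
#' all images of a subject share its fold, so no subject ever contributes
#' to both training and testing. Within each group subjects are shuffled
#' and dealt to the currently smallest folds, giving near-balanced fold
#' sizes (differing by at most one subject) stratified by group.
#'
#' @param metadata data.frame with `subject_id` and `group` columns (one
#'   row per image is fine; subjects are deduplicated).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return A `fold_plan`: list with `n_folds`, `assignment` (named
#'   integer vector subject_id -> fold) and `seed`.
#' @export
make_subject_folds <- function(metadata, n_folds = 10L, seed = 1L) {
  stopifnot(all(c("subject_id", "group") %in% names(metadata)))
  subj <- unique(metadata[, c("subject_id", "group")])
  subj$subject_id <- as.character(subj$subject_id)
  if (anyDuplicated(subj$subject_id))
    stop("a subject appears with more than one group")
  if (nrow(subj) < n_folds)
    stop("fewer subjects (", nrow(subj), ") than folds (", n_folds, ")")
  set.seed(seed)
  assignment <- integer(0)
  load <- integer(n_folds)
  for (g in sort(unique(subj$group))) {
    ids <- sample(subj$subject_id[subj$group == g])
    for (id in ids) {
      f <- which.min(load)  # ties -> lowest fold index
      assignment[id] <- f
      load[f] <- load[f] + 1L
    }
  }
  structure(list(n_folds = as.integer(n_folds), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Train a voting ensemble of MMDNNs
#'
#' The training subjects are randomly divided into `n_members` disjoint
#' sets; member i uses set i for validation (early stopping) and the
#' remaining sets for gradient updates, so every member sees a different
#' train/validation split of the same training pool. When
#' `cfg$standardize` is TRUE, features are standardized with statistics
#' of the whole training pool and the statistics are stored on the
#' ensemble so prediction applies the identical transform.
#'
#' @param features named list of feature matrices over the training
#'   images (rows aligned with `metadata`).
#' @param labels integer 0/1 vector per image.
#' @param metadata data.frame with `subject_id` (and ideally `group`)
#'   per image, same row order as the matrices.
#' @param cfg a [train_config()]; member i trains with seed
#'   `cfg$seed + i`.
#' @param n_members ensemble size (default 10).
#' @return An `ensemble_model`: `members` (list of `mmdnn_model`),
#'   `val_split_ids` (disjoint subject-id sets covering the training
#'   subjects), `standardizer`, `branch_names`, `cfg`.
#' @export
train_ensemble <- function(features, labels, metadata, cfg = train_config(),
                           n_members = 10L) {
  stopifnot("subject_id" %in% names(metadata))
  n <- nrow(features[[1]])
  if (nrow(metadata) != n) stop("metadata rows must match feature rows")
  subjects <- as.character(metadata$subject_id)
  if (length(unique(subjects)) < n_members)
    stop("need at least ", n_members, " training subjects, have ",
         length(unique(subjects)))
  md <- metadata
  if (!"group" %in% names(md)) md$group <- "all"
  split_plan <- make_subject_folds(md, n_folds = n_members, seed = cfg$seed)
  val_split_ids <- lapply(seq_len(n_members), function(i)
    names(split_plan$assignment)[split_plan$assignment == i])

  standardizer <- NULL
  if (isTRUE(cfg$standardize)) {
    fit <- lapply(features, function(f) standardize_features(f))
    features <- lapply(fit, `[[`, "train")
    standardizer <- lapply(fit, function(x) list(center = x$center,
                                                 scale = x$scale))
  }

  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    val_rows <- which(subjects %in% val_split_ids[[i]])
    member_cfg <- cfg
    member_cfg$seed <- cfg$seed + i
    members[[i]] <- train_mmdnn(features, labels, val_rows, member_cfg)
  }
  structure(list(members = members, val_split_ids = val_split_ids,
                 standardizer = standardizer,
                 branch_names = members[[1]]$branch_names, cfg = cfg),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members, branches: %s\n",
              length(x$members), paste(x$branch_names, collapse = ", ")))
  invisible(x)
}

apply_standardizer <- function(features, standardizer) {
  if (is.null(standardizer)) return(features)
  out <- features
  for (nm in names(standardizer)) {
    s <- standardizer[[nm]]
    safe <- ifelse(s$scale > 0, s$scale, 1)
    z <- sweep(sweep(features[[nm]], 2, s$center, "-"), 2, safe, "/")
    z[, s$scale == 0] <- 0
    out[[nm]] <- z
  }
  out
}

#' Ensemble vote by summed probabilities
#'
#' Feeds the images to every member network, adds the ten (or
#' `n_members`) probability pairs, and assigns the class with the highest
#' sum; an exact tie goes to the negative class. The staging score is the
#' summed positive-class probability divided by the number of members, a
#' value in `[0, 1]` with 0 most control-like and 1 most AD-like.
#'
#' @param model an `ensemble_model`.
#' @param features named list of feature matrices for the images to score
#'   (raw scale; the ensemble's stored standardizer is applied).
#' @return data.frame with `image_id`, `summed_p_neg`, `summed_p_pos`,
#'   `label` (0/1) and `staging_score`.
#' @export
ensemble_predict <- function(model, features) {
  stopifnot(inherits(model, "ensemble_model"))
  features <- apply_standardizer(features, model$standardizer)
  total <- NULL
  for (member in model$members) {
    P <- predict_proba(member, features)
    total <- if (is.null(total)) P else total + P
  }
  n_members <- length(model$members)
  ids <- rownames(total)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(total)))
  data.frame(image_id = ids,
             summed_p_neg = total[, 1], summed_p_pos = total[, 2],
             label = as.integer(total[, 2] > total[, 1]),
             staging_score = total[, 2] / n_members,
             row.names = NULL)
}

#' Classification metrics
#'
#' Sensitivity is the fraction of positive-class images correctly
#' classified, specificity the fraction of negative-class images
#' correctly classified, accuracy the fraction correct overall; per-group
#' accuracies are correct/total within each group.
#'
#' @param predictions integer 0/1 predicted labels.
#' @param truth integer 0/1 true labels.
#' @param groups optional per-image group labels.
#' @return A `classification_report`: confusion counts (`tp`, `fp`,
#'   `tn`, `fn`), `sensitivity`, `specificity`, `accuracy`, and
#'   `group_accuracy` when groups are given.
#' @export
compute_metrics <- function(predictions, truth, groups = NULL) {
  if (!length(truth)) stop("empty input")
  if (length(predictions) != length(truth)) stop("length mismatch")
  tp <- sum(predictions == 1 & truth == 1)
  fp <- sum(predictions == 1 & truth == 0)
  tn <- sum(predictions == 0 & truth == 0)
  fn <- sum(predictions == 0 & truth == 1)
  rep <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
              accuracy = (tp + tn) / length(truth))
  if (!is.null(groups)) {
    correct <- predictions == truth
    rep$group_accuracy <- tapply(correct, groups, mean)
  }
  structure(rep, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f (tp %d fp %d tn %d fn %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$tp, x$fp, x$tn, x$fn))
  if (!is.null(x$group_accuracy)) {
    cat("per-group accuracy:\n")
    print(round(x$group_accuracy, 3))
  }
  invisible(x)
}

#' Accuracy binned by years to conversion
#'
#' Bin `y` (y = 1..`max_year`) collects images acquired in the half-open
#' interval `(y-1, y]` years before conversion; bin 0 is reserved for
#' images at or after conversion (a current clinical diagnosis of
#' probable AD). Years beyond `max_year` fall into the last bin.
#'
#' @param correct logical vector, was each image classified correctly.
#' @param years numeric years-to-conversion per image (>= 0).
#' @param groups optional group labels for per-group accuracy curves.
#' @param max_year largest bin (default 8).
#' @return data.frame with `bin`, `n`, `accuracy` (and `group` when
#'   groups are given).
#' @export
accuracy_by_years_to_conversion <- function(correct, years, groups = NULL,
                                            max_year = 8L) {
  if (any(years < 0, na.rm = TRUE)) stop("years to conversion must be >= 0")
  bin <- ifelse(years <= 0, 0L, pmin(as.integer(ceiling(years)), max_year))
  if (is.null(groups)) {
    agg <- tapply(correct, bin, mean)
    cnt <- tapply(correct, bin, length)
    data.frame(bin = as.integer(names(agg)), n = as.integer(cnt),
               accuracy = as.numeric(agg), row.names = NULL)
  } else {
    df <- data.frame(correct = correct, bin = bin, group = groups)
    out <- aggregate(correct ~ group + bin, df,
                     FUN = function(x) c(mean(x), length(x)))
    data.frame(group = out$group, bin = out$bin,
               n = as.integer(out$correct[, 2]),
               accuracy = out$correct[, 1], row.names = NULL)
  }
}

#' Experiment design
#'
#' Two validation designs are supported. `smci_vs_pmci` selects one image
#' per subject (the baseline image for sMCI; for pMCI the earliest image
#' within 3 years before conversion) and runs image-level 10-fold CV over
#' subjects. `snc_vs_positive` trains sNC (negative) against a
#' dementia-positive class enriched in three levels — `"sAD"`,
#' `"pMCI+sAD"`, `"pNC+pMCI+sAD"` — with subject-level folds over the
#' trained groups; progressive groups left out of training are evaluated
#' in every fold and their metrics averaged over folds.
#'
#' @param task `"smci_vs_pmci"` or `"snc_vs_positive"`.
#' @param enrichment positive-class training groups for
#'   `snc_vs_positive`; one of `"sAD"`, `"pMCI+sAD"`, `"pNC+pMCI+sAD"`.
#' @param n_folds number of CV folds.
#' @param n_members ensemble size per fold.
#' @param seed integer seed controlling folds, splits and training.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(task = c("smci_vs_pmci", "snc_vs_positive"),
                              enrichment = c("sAD", "pMCI+sAD", "pNC+pMCI+sAD"),
                              n_folds = 10L, n_members = 10L, seed = 1L) {
  task <- match.arg(task)
  enrichment <- match.arg(enrichment)
  structure(list(task = task,
                 enrichment = if (task == "snc_vs_positive") enrichment else NULL,
                 n_folds = as.integer(n_folds),
                 n_members = as.integer(n_members), seed = as.integer(seed)),
            class = "experiment_design")
}

enrichment_groups <- function(enrichment) {
  switch(enrichment,
         "sAD" = "sAD",
         "pMCI+sAD" = c("pMCI", "sAD"),
         "pNC+pMCI+sAD" = c("pNC", "pMCI", "sAD"),
         stop("unknown enrichment: ", enrichment))
}

# One image per subject for the sMCI-vs-pMCI design: baseline image for
# sMCI; for pMCI the earliest acquired image within 3 years before
# conversion (fallback: the image closest to conversion if none within).
select_mci_images <- function(metadata) {
  pick <- function(rows) {
    if (rows$group[1] == "sMCI") return(rows[which.min(rows$timepoint), ])
    ok <- rows$years_to_conversion <= 3 & rows$years_to_conversion > 0
    if (any(ok)) {
      rows <- rows[ok, , drop = FALSE]
      rows[which.min(rows$timepoint), ]
    } else {
      rows[which.min(rows$years_to_conversion), ]
    }
  }
  md <- metadata[metadata$group %in% c("sMCI", "pMCI"), , drop = FALSE]
  parts <- split(md, md$subject_id, drop = TRUE)
  out <- do.call(rbind, lapply(parts, pick))
  rownames(out) <- NULL
  out
}

#' Run a cross-validation experiment
#'
#' Executes the chosen [experiment_design()] on a dataset: subject-level
#' folds, one voting ensemble trained per fold, fold metrics, pooled
#' summaries and the per-image prediction table.
#'
#' For `snc_vs_positive`, each fold's test set contains all images of the
#' held-out training-design subjects plus all images of the progressive
#' groups excluded from training; sMCI images take no part in this
#' design. Truth labels are positive for pNC, pMCI and sAD images.
#'
#' @param design an [experiment_design()].
#' @param dataset list with `features` (named list of matrices over all
#'   images) and `metadata` (`subject_id`, `image_id`, `group`,
#'   `timepoint`, `years_to_conversion`), rows aligned.
#' @param cfg a [train_config()]; `design$seed` overrides `cfg$seed`.
#' @return An `experiment_result`: `report` (mean and sd of each metric
#'   over folds, plus pooled confusion counts), `fold_reports`,
#'   `predictions` (one row per fold x test image: `fold`, `image_id`,
#'   `subject_id`, `group`, `years_to_conversion`, `truth`, `label`,
#'   `staging_score`) and `design`.
#' @export
run_experiment <- function(design, dataset, cfg = train_config()) {
  stopifnot(inherits(design, "experiment_design"))
  metadata <- dataset$metadata
  features <- dataset$features
  if (nrow(features[[1]]) != nrow(metadata))
    stop("features and metadata must have aligned rows")
  cfg$seed <- design$seed

  if (design$task == "smci_vs_pmci") {
    sel <- select_mci_images(metadata)
    if (!nrow(sel)) stop("no sMCI/pMCI images in dataset")
    rows <- match(sel$image_id, metadata$image_id)
    md <- metadata[rows, , drop = FALSE]
    feats <- lapply(features, function(f) f[rows, , drop = FALSE])
    truth <- as.integer(md$group == "pMCI")
    never_rows <- integer(0)
    fold_md <- md
  } else {
    pos_groups <- c("pNC", "pMCI", "sAD")
    trained_groups <- c("sNC", enrichment_groups(design$enrichment))
    keep <- metadata$group %in% c("sNC", pos_groups)
    md <- metadata[keep, , drop = FALSE]
    feats <- lapply(features, function(f) f[keep, , drop = FALSE])
    truth <- as.integer(md$group %in% pos_groups)
    in_design <- md$group %in% trained_groups
    never_rows <- which(!in_design)
    fold_md <- md[in_design, , drop = FALSE]
  }
  if (!nrow(fold_md)) stop("no images available for the training design")

  plan <- make_subject_folds(fold_md, n_folds = design$n_folds,
                             seed = design$seed)
  fold_of <- plan$assignment[as.character(md$subject_id)]  # NA: never-trained

  fold_reports <- vector("list", design$n_folds)
  predictions <- list()
  for (f in seq_len(design$n_folds)) {
    test_rows <- sort(c(which(fold_of == f), never_rows))
    train_rows <- which(fold_of != f & !is.na(fold_of))
    if (length(intersect(md$subject_id[train_rows], md$subject_id[test_rows])))
      stop("internal error: subject leakage between train and test")
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + 1000L * f
    ens <- train_ensemble(lapply(feats, function(x) x[train_rows, , drop = FALSE]),
                          truth[train_rows], md[train_rows, , drop = FALSE],
                          fold_cfg, n_members = design$n_members)
    pred <- ensemble_predict(ens, lapply(feats, function(x)
      x[test_rows, , drop = FALSE]))
    fold_reports[[f]] <- compute_metrics(pred$label, truth[test_rows],
                                         md$group[test_rows])
    predictions[[f]] <- data.frame(fold = f,
                                   image_id = md$image_id[test_rows],
                                   subject_id = md$subject_id[test_rows],
                                   group = md$group[test_rows],
                                   years_to_conversion =
                                     md$years_to_conversion[test_rows],
                                   truth = truth[test_rows],
                                   label = pred$label,
                                   staging_score = pred$staging_score,
                                   row.names = NULL)
  }
  predictions <- do.call(rbind, predictions)

  metric_mat <- vapply(fold_reports, function(r)
    c(accuracy = r$accuracy, sensitivity = r$sensitivity,
      specificity = r$specificity), numeric(3))
  report <- list(mean = rowMeans(metric_mat, na.rm = TRUE),
                 sd = apply(metric_mat, 1, sd, na.rm = TRUE),
                 pooled = compute_metrics(predictions$label,
                                          predictions$truth,
                                          predictions$group))
  structure(list(report = report, fold_reports = fold_reports,
                 predictions = predictions, design = design),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s%s, %d folds x %d members\n",
              x$design$task,
              if (!is.null(x$design$enrichment))
                paste0(" [", x$design$enrichment, "]") else "",
              x$design$n_folds, x$design$n_members))
  m <- x$report$mean; s <- x$report$sd
  cat(sprintf("  accuracy %.3f (%.3f) | sensitivity %.3f (%.3f) | specificity %.3f (%.3f)\n",
              m["accuracy"], s["accuracy"], m["sensitivity"], s["sensitivity"],
              m["specificity"], s["specificity"]))
  invisible(x)
}

#' Mean staging score per diagnostic group
#'
#' Averages each image's staging score over the folds that tested it
#' (never-trained groups are scored in every fold), then averages within
#' groups. On a staged cohort the expected ordering is
#' sNC < pNC < pMCI < sAD.
#'
#' @param predictions the `predictions` table of an `experiment_result`.
#' @return data.frame with `group`, `n_images`, `mean_staging`.
#' @export
staging_by_group <- function(predictions) {
  per_image <- aggregate(staging_score ~ image_id + group, predictions, mean)
  agg <- aggregate(staging_score ~ group, per_image, mean)
  cnt <- aggregate(image_id ~ group, per_image, length)
  data.frame(group = agg$group, n_images = cnt$image_id,
             mean_staging = agg$staging_score, row.names = NULL)
}
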