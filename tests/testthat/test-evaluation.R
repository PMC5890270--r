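test_that("fold plans keep subjects intact and balance fold sizes", {
  md <- data.frame(subject_id = rep(sprintf("S%02d", 1:20), each = 3),
                   image_id = sprintf("I%02d", 1:60),
                   group = rep(rep(c("sNC", "sAD"), each = 10), each = 3))
  plan <- make_subject_folds(md, n_folds = 10, seed = 4)
  expect_length(plan$assignment, 20)
  sizes <- table(plan$assignment)
  expect_identical(as.integer(sizes), rep(2L, 10))  # 20 subjects, 10 folds
  # all images of a subject share the subject's fold by construction
  img_fold <- plan$assignment[md$subject_id]
  expect_identical(as.integer(tapply(img_fold, md$subject_id,
                                     function(x) length(unique(x)))),
                   rep(1L, 20))
  expect_error(make_subject_folds(md[1:9, ], n_folds = 10), "fewer subjects")
})

test_that("fold sizes differ by at most one under awkward group sizes", {
  md <- data.frame(subject_id = sprintf("S%02d", 1:23),
                   group = c(rep("sNC", 7), rep("sAD", 9), rep("pMCI", 7)))
  plan <- make_subject_folds(md, n_folds = 5, seed = 1)
  sizes <- table(factor(plan$assignment, levels = 1:5))
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("classification metrics match their definitions and a counting oracle", {
  pred <- c(rep(1, 90), rep(0, 10), rep(0, 80), rep(1, 20))
  truth <- c(rep(1, 100), rep(0, 100))
  rep_ <- compute_metrics(pred, truth)
  expect_equal(rep_$sensitivity, 0.90)
  expect_equal(rep_$specificity, 0.80)
  expect_equal(rep_$accuracy, 0.85)

  all_good <- compute_metrics(truth, truth)
  expect_equal(all_good$accuracy, 1)
  expect_equal(all_good$sensitivity, 1)
  expect_equal(all_good$specificity, 1)

  set.seed(10)
  for (i in 1:5) {
    n <- 50
    p <- sample(0:1, n, TRUE); t_ <- sample(0:1, n, TRUE)
    g <- sample(c("a", "b"), n, TRUE)
    r <- compute_metrics(p, t_, g)
    expect_identical(r$tp, sum(p == 1 & t_ == 1))
    expect_identical(r$tn, sum(p == 0 & t_ == 0))
    expect_equal(r$accuracy, mean(p == t_))
    expect_equal(unname(r$group_accuracy["a"]), mean((p == t_)[g == "a"]))
  }
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
})

test_that("year bins are half-open with bin 0 for post-conversion images", {
  correct <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  years <- c(0.5, 1.0, 1.2, 0, 2.0)
  out <- accuracy_by_years_to_conversion(correct, years)
  expect_identical(out$bin, c(0L, 1L, 2L))
  expect_equal(out$accuracy[out$bin == 1], 1)    # 0.5 and 1.0 both in bin 1
  expect_equal(out$n[out$bin == 1], 2L)
  expect_equal(out$accuracy[out$bin == 2], 0)    # 1.2 and 2.0 in bin 2, one wrong
  expect_error(accuracy_by_years_to_conversion(TRUE, -1), ">= 0")

  # a bin with 4 of 5 correct scores 0.8
  out2 <- accuracy_by_years_to_conversion(c(TRUE, TRUE, TRUE, TRUE, FALSE),
                                          rep(2.5, 5))
  expect_equal(out2$accuracy, 0.8)

  # pooled bins reproduce the overall accuracy (weighted average oracle)
  set.seed(11)
  correct <- sample(c(TRUE, FALSE), 200, TRUE)
  years <- runif(200, 0, 8)
  out3 <- accuracy_by_years_to_conversion(correct, years)
  expect_equal(sum(out3$accuracy * out3$n) / sum(out3$n), mean(correct))
})

test_that("the pMCI image selection rule picks the earliest image within 3 years", {
  md <- data.frame(
    subject_id = c("A", "A", "A", "B", "B", "C"),
    image_id = c("A0", "A1", "A2", "B0", "B1", "C0"),
    group = c("pMCI", "pMCI", "pMCI", "pMCI", "pMCI", "sMCI"),
    timepoint = c(0, 1, 2, 0, 1, 0),
    years_to_conversion = c(5, 2.8, 1.8, 6, 4.5, NA))
  sel <- mmdnn:::select_mci_images(md)
  # subject A: earliest timepoint among those with years <= 3 is A1
  expect_identical(sel$image_id[sel$subject_id == "A"], "A1")
  # subject B: none within 3 years -> closest to conversion
  expect_identical(sel$image_id[sel$subject_id == "B"], "B1")
  # sMCI: baseline image
  expect_identical(sel$image_id[sel$subject_id == "C"], "C0")
})

test_that("ensemble voting sums probabilities with ties to the negative class", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 70))
  rows <- which(sim$metadata$group %in% c("sNC", "sAD"))
  labels <- as.integer(sim$metadata$group[rows] == "sAD")
  feats <- lapply(sim$features[c("volume_40", "metabolism_40")],
                  function(f) f[rows, , drop = FALSE])
  md <- sim$metadata[rows, ]
  ens <- train_ensemble(feats, labels, md, tiny_cfg(2), n_members = 2)
  # member validation splits are disjoint subject sets covering the pool
  expect_length(intersect(ens$val_split_ids[[1]], ens$val_split_ids[[2]]), 0)
  expect_setequal(unlist(ens$val_split_ids), unique(md$subject_id))

  pred <- ensemble_predict(ens, feats)
  std <- mmdnn:::apply_standardizer(feats, ens$standardizer)
  manual <- predict_proba(ens$members[[1]], std) +
    predict_proba(ens$members[[2]], std)
  expect_equal(pred$summed_p_pos, unname(manual[, 2]), tolerance = 1e-12)
  expect_equal(pred$staging_score, unname(manual[, 2]) / 2, tolerance = 1e-12)
  expect_identical(pred$label, as.integer(manual[, 2] > manual[, 1]))

  # force an exact tie: zero fusion heads give (0.5, 0.5) from every member
  tied <- ens
  for (i in seq_along(tied$members)) {
    tied$members[[i]]$fusion$head$W[] <- 0
    tied$members[[i]]$fusion$head$b[] <- 0
  }
  pred_tied <- ensemble_predict(tied, feats)
  expect_true(all(pred_tied$label == 0L))
  expect_equal(pred_tied$staging_score, rep(0.5, nrow(pred_tied)))
})

test_that("ensembles reuse exactly the same member splits on rerun", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 71))
  rows <- which(sim$metadata$group %in% c("sNC", "sAD"))
  labels <- as.integer(sim$metadata$group[rows] == "sAD")
  feats <- lapply(sim$features["volume_40"], function(f) f[rows, , drop = FALSE])
  md <- sim$metadata[rows, ]
  e1 <- train_ensemble(feats, labels, md, tiny_cfg(6), n_members = 2)
  e2 <- train_ensemble(feats, labels, md, tiny_cfg(6), n_members = 2)
  expect_identical(e1$val_split_ids, e2$val_split_ids)
  p1 <- ensemble_predict(e1, feats); p2 <- ensemble_predict(e2, feats)
  expect_identical(p1, p2)
})

test_that("the MCI experiment tests every subject exactly once without leakage", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 72))
  design <- experiment_design("smci_vs_pmci", n_folds = 4, n_members = 2,
                              seed = 5)
  res <- run_experiment(design, list(features = sim$features,
                                     metadata = sim$metadata), tiny_cfg())
  pred <- res$predictions
  # one image per subject, each tested exactly once
  expect_identical(sort(unique(pred$subject_id)),
                   sort(unique(sim$metadata$subject_id[
                     sim$metadata$group %in% c("sMCI", "pMCI")])))
  expect_identical(anyDuplicated(pred$image_id), 0L)
  expect_identical(sort(unique(pred$fold)), 1:4)
  expect_length(res$fold_reports, 4)
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in%
                    names(res$report$mean)))
})

test_that("never-trained groups are tested in every fold of the enriched design", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 73))
  design <- experiment_design("snc_vs_positive", enrichment = "sAD",
                              n_folds = 3, n_members = 2, seed = 2)
  res <- run_experiment(design, list(features = sim$features,
                                     metadata = sim$metadata), tiny_cfg())
  pred <- res$predictions
  expect_false(any(pred$group == "sMCI"))  # sMCI takes no part
  # pNC and pMCI (never trained at this level) appear in every fold
  for (f in 1:3) {
    in_fold <- pred[pred$fold == f, ]
    expect_setequal(unique(in_fold$group[in_fold$group %in% c("pNC", "pMCI")]),
                    c("pNC", "pMCI"))
  }
  pnc_imgs <- sim$metadata$image_id[sim$metadata$group == "pNC"]
  expect_identical(sum(pred$group == "pNC"), 3L * length(pnc_imgs))
  # trained-design groups tested exactly once each
  snc_pred <- pred[pred$group == "sNC", ]
  expect_identical(anyDuplicated(snc_pred$image_id), 0L)
  # truth labels follow group membership
  expect_true(all(pred$truth[pred$group == "sNC"] == 0))
  expect_true(all(pred$truth[pred$group != "sNC"] == 1))
})

test_that("fully enriched design tests each subject exactly once", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 74))
  design <- experiment_design("snc_vs_positive", enrichment = "pNC+pMCI+sAD",
                              n_folds = 3, n_members = 2, seed = 2)
  res <- run_experiment(design, list(features = sim$features,
                                     metadata = sim$metadata), tiny_cfg())
  pred <- res$predictions
  expect_identical(anyDuplicated(pred$image_id), 0L)
  expect_setequal(unique(pred$group), c("sNC", "pNC", "pMCI", "sAD"))
  # staging summary covers all four groups
  st <- staging_by_group(pred)
  expect_setequal(st$group, c("sNC", "pNC", "pMCI", "sAD"))
  expect_true(all(st$mean_staging >= 0 & st$mean_staging <= 1))
})

test_that("ensemble voting is no less stable than a single network", {
  # moderate effect so accuracy is off both floor and ceiling
  ens_acc <- c(); single_acc <- c()
  for (seed in 1:5) {
    cfg <- small_sim_cfg(seed = 400 + seed, delta_vol = 0.12, delta_met = 0.12,
                         group_sizes = c(sNC = 14, sAD = 14),
                         images_per_subject = c(1, 1))
    sim <- simulate_feature_tables(cfg)
    md <- sim$metadata
    labels <- as.integer(md$group == "sAD")
    set.seed(seed)
    test_subj <- sample(unique(md$subject_id), 8)
    te <- which(md$subject_id %in% test_subj)
    tr <- setdiff(seq_len(nrow(md)), te)
    cfg_tr <- desk_cfg(seed)
    ens <- train_ensemble(lapply(sim$features, function(f) f[tr, , drop = FALSE]),
                          labels[tr], md[tr, ], cfg_tr, n_members = 4)
    pred <- ensemble_predict(ens, lapply(sim$features,
                                         function(f) f[te, , drop = FALSE]))
    ens_acc <- c(ens_acc, mean(pred$label == labels[te]))
    std <- mmdnn:::apply_standardizer(lapply(sim$features,
                                             function(f) f[te, , drop = FALSE]),
                                      ens$standardizer)
    P1 <- predict_proba(ens$members[[1]], std)
    single_acc <- c(single_acc, mean((P1[, 2] > 0.5) == (labels[te] == 1)))
  }
  expect_lte(sd(ens_acc), sd(single_acc) + 1e-9)
})

test_that("experiments are reproducible seed for seed", {
  sim <- simulate_feature_tables(small_sim_cfg(seed = 75))
  design <- experiment_design("smci_vs_pmci", n_folds = 2, n_members = 2,
                              seed = 9)
  ds <- list(features = sim$features, metadata = sim$metadata)
  r1 <- run_experiment(design, ds, tiny_cfg())
  r2 <- run_experiment(design, ds, tiny_cfg())
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(r1$report, r2$report)
})
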