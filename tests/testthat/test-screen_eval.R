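# small labelled design shared across tests: n rows, f features
toy_matrix <- function(n_pos, n_neg, n_feat = 5L, seed = 1L) {
  set.seed(seed)
  mat <- matrix(rbinom((n_pos + n_neg) * n_feat, 1L, 0.4),
                ncol = n_feat,
                dimnames = list(sprintf("t%03d", seq_len(n_pos + n_neg)),
                                sprintf("F:%d", seq_len(n_feat))))
  list(features = mat,
       labels = rep(c("positive", "negative"), c(n_pos, n_neg)))
}

test_that("rank AUC and AUPR agree with reference computations", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (i in 1:10) {
    labels <- sample(c("positive", "negative"), 40, TRUE)
    scores <- round(runif(40), 2)  # coarse grid forces ties
    if (length(unique(labels)) < 2L) next
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, quiet = TRUE,
      levels = c("negative", "positive"), direction = "<")))
    expect_equal(kgscreen:::.auc(labels, scores), ref)
  }
  # AUPR hand-computed: scores rank pos, neg, pos, neg ->
  # precision at recall 1/2 is 1/1, at recall 2/2 is 2/3
  labs <- c("positive", "negative", "positive", "negative")
  sc <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(kgscreen:::.aupr(labs, sc), 0.5 * 1 + 0.5 * (2 / 3))
  # perfect ranking gives AUPR 1, and ties collapse to one threshold
  expect_equal(kgscreen:::.aupr(c("positive", "negative"), c(1, 0)), 1)
  expect_equal(kgscreen:::.aupr(c("positive", "negative"), c(0.5, 0.5)), 0.5)
})

test_that("negative sampling is sized, uniform, and seed-stable", {
  pool <- lapply(1:50, function(i)
    combination(paste0("n", i), "A", "B", "negative"))
  pos <- lapply(1:10, function(i)
    combination(paste0("p", i), "A", "B", "positive"))
  s1 <- sample_negatives(pos, pool, ratio = 1, seed = 3)
  expect_length(s1, 10L)
  expect_identical(combo_ids(s1),
                   combo_ids(sample_negatives(pos, pool, ratio = 1, seed = 3)))
  expect_length(sample_negatives(pos, pool, ratio = 5, seed = 3), 50L)
  expect_error(sample_negatives(pos, pool, ratio = 6, seed = 3), "too small")
  # different seeds give different draws (overwhelmingly likely)
  s2 <- sample_negatives(pos, pool, ratio = 1, seed = 4)
  expect_false(identical(combo_ids(s1), combo_ids(s2)))
})

test_that("a perfectly separable feature yields AUC and AUPR of 100%", {
  d <- toy_matrix(15, 40, seed = 2)
  d$features[, 1L] <- as.integer(d$labels == "positive")
  res <- run_repeated_cv(d$features, d$labels,
                         cv_config(n_repeats = 2L, n_folds = 5L,
                                   n_trees = 100L, seed = 11L))
  expect_equal(res$mean_auc, 100)
  expect_equal(res$mean_aupr, 100)
  # and the separating column dominates the importance ranking
  top <- rank_feature_importance(res, 3L)
  expect_equal(top$id[1L], "F:1")
  expect_equal(max(res$importance), 1)
})

test_that("label-shuffled features score near chance", {
  d <- toy_matrix(30, 90, n_feat = 8L, seed = 3)
  res <- run_repeated_cv(d$features, sample(d$labels),
                         cv_config(n_repeats = 5L, n_folds = 5L,
                                   n_trees = 100L, seed = 21L))
  expect_lt(abs(res$mean_auc - 50), 3 * max(res$sd_auc, 3))
})

test_that("results are bit-reproducible under the same master seed", {
  d <- toy_matrix(12, 36, seed = 4)
  cfg <- cv_config(n_repeats = 3L, n_folds = 4L, n_trees = 50L, seed = 31L)
  r1 <- run_repeated_cv(d$features, d$labels, cfg)
  r2 <- run_repeated_cv(d$features, d$labels, cfg)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_identical(r1$oof, r2$oof)
  expect_identical(r1$importance, r2$importance)
})

test_that("importance ranking validates input and truncates politely", {
  d <- toy_matrix(10, 20, n_feat = 3L, seed = 5)
  res <- run_repeated_cv(d$features, d$labels,
                         cv_config(n_repeats = 1L, n_folds = 3L,
                                   n_trees = 50L, seed = 41L))
  expect_warning(top <- rank_feature_importance(res, 10L), "truncating")
  expect_equal(nrow(top), 3L)
  expect_true(all(diff(top$importance) <= 0))
})

test_that("stratified AUC collapses to the overall AUC for one stratum", {
  g <- random_test_graph(20, 60, seed = 81)
  combos <- lapply(1:24, function(i) {
    cb <- random_test_combo(g, 2, 2, seed = 200 + i)  # all two-target
    cb$label <- if (i <= 12) "positive" else "negative"
    cb$combo_id <- sprintf("t%03d", i)
    cb
  })
  spec <- build_feature_space(g, "full")
  mat <- extract_feature_matrix(combos, g, spec)
  res <- run_repeated_cv(mat, combo_labels(combos),
                         cv_config(n_repeats = 3L, n_folds = 4L,
                                   n_trees = 50L, seed = 51L))
  strat <- stratified_auc(res, combos)
  expect_equal(strat$bin, "2")
  expect_equal(strat$mean_auc, res$mean_auc)
  expect_equal(strat$n_repeats_used, 3L)
})

test_that("per-stratum AUC equals a direct rank-based recomputation", {
  d <- toy_matrix(20, 60, seed = 6)
  combos <- lapply(seq_len(nrow(d$features)), function(i)
    combination(rownames(d$features)[i],
                sprintf("X%d", seq_len(1L + (i %% 4))), "Y", d$labels[i]))
  res <- run_repeated_cv(d$features, d$labels,
                         cv_config(n_repeats = 2L, n_folds = 5L,
                                   n_trees = 50L, seed = 61L))
  strat <- stratified_auc(res, combos)
  n_targets <- vapply(combos, function(cb) length(cb$drug_targets), 1L)
  names(n_targets) <- combo_ids(combos)
  for (b in strat$bin) {
    keep <- switch(b, "1" = n_targets == 1L, "2" = n_targets == 2L,
                   n_targets > 2L)
    ids <- names(n_targets)[keep]
    aucs <- vapply(split(res$oof, res$oof$repeat_id), function(dd) {
      dd <- dd[dd$combo_id %in% ids, ]
      if (length(unique(dd$label)) < 2L) return(NA_real_)
      100 * kgscreen:::.auc(dd$label, dd$score)
    }, 0)
    expect_equal(strat$mean_auc[strat$bin == b], mean(aucs, na.rm = TRUE))
  }
})

test_that("single-class strata are skipped with a message", {
  d <- toy_matrix(10, 30, seed = 7)
  combos <- lapply(seq_len(nrow(d$features)), function(i)
    combination(rownames(d$features)[i],
                # positives single-target, negatives two-target
                if (d$labels[i] == "positive") "X1" else c("X1", "X2"),
                "Y", d$labels[i]))
  res <- run_repeated_cv(d$features, d$labels,
                         cv_config(n_repeats = 2L, n_folds = 5L,
                                   n_trees = 50L, seed = 71L))
  expect_message(strat <- stratified_auc(res, combos), "lacked both classes")
  expect_true(all(is.na(strat$mean_auc)))
})

test_that("ratio 1 reproduces the plain repeated CV exactly", {
  d <- toy_matrix(10, 60, seed = 8)
  cfg <- cv_config(n_repeats = 2L, n_folds = 5L, n_trees = 50L, seed = 81L)
  base <- run_repeated_cv(d$features, d$labels, cfg)
  ratio <- ratio_experiment(d$features, d$labels, ratios = c(1, 3), cfg)
  expect_identical(ratio$results[[1L]]$per_repeat, base$per_repeat)
  expect_equal(ratio$summary$ratio, c(1, 3))
  # separable data stays perfect at every ratio
  d$features[, 1L] <- as.integer(d$labels == "positive")
  sep <- ratio_experiment(d$features, d$labels, ratios = c(1, 3, 5), cfg)
  expect_true(all(sep$summary$mean_auc == 100))
  expect_error(ratio_experiment(d$features, d$labels, ratios = 7, cfg),
               "feasible maximum ratio")
})

test_that("ablating a source the signal depends on destroys it", {
  # planted dependency: label = presence of a direct triple attested only by
  # SRC_sig; ablating SRC_sig must drop AUC to chance, ablating the
  # redundant SRC_dup (signal duplicated) must not
  set.seed(91)
  prot <- sprintf("Q%02d", 1:40)
  rows <- list()
  combos <- list()
  for (i in 1:30) {
    dt <- sample(prot, 2L); dp <- sample(setdiff(prot, dt), 2L)
    pos <- i <= 15
    if (pos)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = dt[1L], predicate = "sig_pred", object = dp[1L],
        provenance = "SRC_sig;SRC_dup")
    rows[[length(rows) + 1L]] <- data.frame(
      subject = dt[2L], predicate = "bg_pred", object = dp[2L],
      provenance = "SRC_bg")
    combos[[i]] <- combination(sprintf("q%02d", i), dt, dp,
                               if (pos) "positive" else "negative")
  }
  g <- kg_graph(do.call(rbind, rows), proteins = prot)
  cfg <- cv_config(n_repeats = 3L, n_folds = 5L, n_trees = 100L, seed = 5L)
  dup <- ablate_source(g, combos, "SRC_dup", cfg)
  expect_gt(dup$ablated$mean_auc, 85)
  expect_lt(abs(dup$delta_auc), 2 * max(dup$full$sd_auc, 2))
  # now make the signal depend solely on SRC_sig
  rows2 <- lapply(rows, function(r) {
    r$provenance <- sub(";SRC_dup", "", r$provenance)
    r
  })
  g2 <- kg_graph(do.call(rbind, rows2), proteins = prot,
                 sources = c("SRC_sig", "SRC_dup", "SRC_bg"))
  sole <- ablate_source(g2, combos, "SRC_sig", cfg)
  expect_gt(sole$full$mean_auc, 85)
  expect_lt(sole$ablated$mean_auc, 65)
  expect_true(any(grepl("sig_pred", sole$dropped_features)))
})
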