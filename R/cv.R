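#' Cross-validation configuration
#'
#' Defaults follow the screening protocol: 100 repeats of 10-fold
#' cross-validation, a fresh balanced negative sample per repeat, random
#' forests of 500 trees.
#'
#' @param n_repeats number of repeated cross-validation experiments
#' @param n_folds folds per experiment (>= 2), stratified by label
#' @param neg_pos_ratio negatives per positive in the *training* folds
#'   (>= 1); test folds always stay balanced 1:1
#' @param n_trees trees per random forest
#' @param seed master integer seed; every repeat, fold split, negative sample
#'   and forest derives its randomness from it
#' @param resample_negatives draw a fresh negative sample each repeat
#'   (default) or reuse the first repeat's sample
#' @return List of class `kg_cv_config`.
#' @export
cv_config <- function(n_repeats = 100L, n_folds = 10L, neg_pos_ratio = 1,
                      n_trees = 500L, seed = 1L, resample_negatives = TRUE) {
  stopifnot(n_folds >= 2L, neg_pos_ratio >= 1, n_repeats >= 1L, n_trees >= 1L)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 neg_pos_ratio = neg_pos_ratio,
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 resample_negatives = isTRUE(resample_negatives)),
            class = "kg_cv_config")
}

#' Sample negative combinations for a balanced experiment
#'
#' Uniform sample without replacement from the negative pool, sized
#' `ratio * length(positives)`; deterministic given the seed.
#'
#' @param positives list of positive [combination()] objects
#' @param negative_pool list of negative combinations to sample from
#' @param ratio negatives per positive
#' @param seed integer seed
#' @return A list of sampled negative combinations.
#' @export
sample_negatives <- function(positives, negative_pool, ratio = 1, seed = 1L) {
  n <- as.integer(round(ratio * length(positives)))
  if (n > length(negative_pool))
    stop("negative pool (", length(negative_pool),
         ") too small for ", n, " negatives")
  set.seed(seed)
  negative_pool[sample.int(length(negative_pool), n)]
}

# ROC AUC via the rank (Mann-Whitney) statistic with midrank tie handling;
# equals the trapezoidal area under the ROC curve. Returns a proportion.
.auc <- function(labels, scores) {
  pos <- labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve as average precision: precision at
# each threshold weighted by the recall increment, with tied scores collapsed
# into one threshold. Positive class convention.
.aupr <- function(labels, scores) {
  pos <- labels == "positive"
  P <- sum(pos)
  if (P == 0L || all(pos)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

# Shared engine behind run_repeated_cv and ratio_experiment. `features` holds
# all candidate rows (positives plus the whole negative pool); each repeat
# draws its own balanced evaluation negatives plus (ratio-1) x n_pos
# train-only negatives, splits the balanced set into stratified folds, and
# scores each held-out fold with a forest trained on the rest.
.cv_engine <- function(features, labels, config, ratio = 1) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- paste0("row", seq_len(nrow(features)))
  stopifnot(length(labels) == nrow(features))
  pos_idx <- which(labels == "positive")
  neg_idx <- which(labels == "negative")
  n_pos <- length(pos_idx)
  if (n_pos < 2L || length(neg_idx) < 2L)
    stop("need at least 2 combinations per class")
  n_eval_neg <- n_pos
  n_extra <- as.integer(round((ratio - 1) * n_pos))
  if (n_eval_neg + n_extra > length(neg_idx))
    stop("negative pool too small: ratio ", ratio, " needs ",
         n_eval_neg + n_extra, " negatives, pool has ", length(neg_idx),
         " (feasible maximum ratio ",
         floor(length(neg_idx) / n_pos * 100) / 100, ")")
  k <- config$n_folds
  per_repeat <- vector("list", config$n_repeats)
  oof <- vector("list", config$n_repeats)
  imp_sum <- NULL
  n_forests <- 0L
  eval_neg <- NULL; extra_neg <- NULL
  for (r in seq_len(config$n_repeats)) {
    set.seed(config$seed + r)
    if (config$resample_negatives || is.null(eval_neg)) {
      eval_neg <- sample(neg_idx, n_eval_neg)
      extra_neg <- if (n_extra > 0L)
        sample(setdiff(neg_idx, eval_neg), n_extra) else integer()
    }
    eval_idx <- c(pos_idx, eval_neg)
    fold <- integer(length(eval_idx))
    fold[seq_len(n_pos)] <- sample(rep_len(seq_len(k), n_pos))
    fold[-seq_len(n_pos)] <- sample(rep_len(seq_len(k), n_eval_neg))
    scores <- numeric(length(eval_idx))
    for (f in seq_len(k)) {
      train_rows <- c(eval_idx[fold != f], extra_neg)
      y_train <- factor(labels[train_rows], levels = c("negative", "positive"))
      if (length(unique(y_train)) < 2L) {
        # degenerate split: re-deal the folds with an offset seed
        set.seed(config$seed + r + 7919L)
        fold[seq_len(n_pos)] <- sample(rep_len(seq_len(k), n_pos))
        fold[-seq_len(n_pos)] <- sample(rep_len(seq_len(k), n_eval_neg))
        message("repeat ", r, ": single-class training fold, re-split")
        train_rows <- c(eval_idx[fold != f], extra_neg)
        y_train <- factor(labels[train_rows],
                          levels = c("negative", "positive"))
      }
      fit <- ranger::ranger(
        x = features[train_rows, , drop = FALSE], y = y_train,
        num.trees = config$n_trees, probability = TRUE,
        importance = "impurity", num.threads = 1L,
        seed = (config$seed * 1009L + r * 101L + f) %% 2147483647L)
      pred <- stats::predict(fit, features[eval_idx[fold == f], , drop = FALSE],
                             num.threads = 1L)$predictions
      scores[fold == f] <- pred[, "positive"]
      imp <- fit$variable.importance
      imp_sum <- if (is.null(imp_sum)) imp else imp_sum + imp
      n_forests <- n_forests + 1L
    }
    eval_labels <- labels[eval_idx]
    per_repeat[[r]] <- data.frame(
      repeat_id = r,
      auc = 100 * .auc(eval_labels, scores),
      aupr = 100 * .aupr(eval_labels, scores))
    oof[[r]] <- data.frame(repeat_id = r,
                           combo_id = rownames(features)[eval_idx],
                           label = eval_labels, score = scores,
                           stringsAsFactors = FALSE)
  }
  per_repeat <- do.call(rbind, per_repeat)
  imp_mean <- imp_sum / n_forests
  importance <- if (max(imp_mean) > 0) imp_mean / max(imp_mean) else imp_mean
  structure(list(
    per_repeat = per_repeat,
    mean_auc = mean(per_repeat$auc), sd_auc = stats::sd(per_repeat$auc),
    mean_aupr = mean(per_repeat$aupr), sd_aupr = stats::sd(per_repeat$aupr),
    oof = do.call(rbind, oof),
    importance = importance,
    config = config, ratio = ratio), class = "kg_cv_result")
}

#' Repeated balanced cross-validation with random forests
#'
#' Each repeat draws a fresh equally-sized sample of negatives (all positives
#' are always used), splits positives and negatives into stratified folds,
#' trains a probability random forest on the remaining folds and scores the
#' held-out fold; ROC AUC and precision-recall AUC are computed per repeat
#' over that repeat's out-of-fold scores. Feature importance (mean decrease
#' in node impurity) is averaged over every trained forest and normalized by
#' its maximum. Fully reproducible from the config seed.
#'
#' @param features 0/1 feature matrix over all positives and the whole
#'   negative pool (rows named by combo id; e.g. from
#'   [extract_feature_matrix()])
#' @param labels character vector, `"positive"`/`"negative"`, aligned with
#'   the rows
#' @param config a [cv_config()]
#' @return Object of class `kg_cv_result`: per-repeat AUC/AUPR (percent),
#'   their means and standard deviations, pooled out-of-fold scores
#'   (`$oof`: repeat_id, combo_id, label, score) and normalized feature
#'   importances.
#' @export
run_repeated_cv <- function(features, labels, config = cv_config()) {
  .cv_engine(features, labels, config, ratio = config$neg_pos_ratio)
}

#' @export
print.kg_cv_result <- function(x, ...) {
  cat(sprintf("<kg_cv_result> %d repeats x %d folds: AUC %.1f%% (%.1f%%), AUPR %.1f%% (%.1f%%)\n",
              x$config$n_repeats, x$config$n_folds, x$mean_auc, x$sd_auc,
              x$mean_aupr, x$sd_aupr))
  invisible(x)
}

#' Rank features by normalized random-forest importance
#'
#' @param result a [run_repeated_cv()] result
#' @param top_k how many features to return (truncated with a warning when
#'   larger than the feature count)
#' @return data.frame: rank, id, slot, kind, value, importance (max = 1),
#'   in descending importance with ties broken by feature order.
#' @export
rank_feature_importance <- function(result, top_k = 20L) {
  imp <- result$importance
  if (is.null(imp)) stop("result carries no importances")
  if (top_k > length(imp)) {
    warning("top_k (", top_k, ") exceeds feature count (", length(imp),
            "); truncating")
    top_k <- length(imp)
  }
  ord <- order(-imp, seq_along(imp))[seq_len(top_k)]
  parts <- strsplit(names(imp)[ord], ":", fixed = TRUE)
  data.frame(rank = seq_len(top_k), id = names(imp)[ord],
             slot = vapply(parts, `[[`, "", 1L),
             kind = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", ""),
             value = vapply(parts, function(p) if (length(p) > 2L) p[[3L]] else "", ""),
             importance = unname(imp[ord]), stringsAsFactors = FALSE)
}

#' Leave one knowledge source out and re-evaluate
#'
#' Removes every feature derivable only from `source` (see
#' [restrict_to_sources()]) and reruns the cross-validation, reporting the
#' AUC change against the unablated run under the same configuration. The
#' default configuration is 10 repeats of 10-fold cross-validation.
#'
#' @param graph a [kg_graph()]
#' @param combos list of [combination()] objects (positives plus negative
#'   pool)
#' @param source the source label to exclude
#' @param config a [cv_config()]; default 10 repeats
#' @param variant feature-space variant (default `"full"`)
#' @return List with `full` and `ablated` `kg_cv_result`s and `delta_auc`
#'   (ablated minus full, percentage points).
#' @export
ablate_source <- function(graph, combos, source,
                          config = cv_config(n_repeats = 10L),
                          variant = "full") {
  spec <- build_feature_space(graph, variant)
  full_mat <- extract_feature_matrix(combos, graph, spec)
  labels <- combo_labels(combos)
  res_full <- run_repeated_cv(full_mat, labels, config)
  abl <- restrict_to_sources(spec, combos, graph, source)
  res_abl <- run_repeated_cv(abl$features, labels, config)
  list(full = res_full, ablated = res_abl,
       delta_auc = res_abl$mean_auc - res_full$mean_auc,
       dropped_features = setdiff(spec$id, abl$spec$id))
}

#' Per-stratum AUC by number of drug targets
#'
#' Splits combinations into the strata "1", "2" and ">2" drug targets and
#' recomputes each repeat's AUC from its out-of-fold scores restricted to the
#' stratum; strata lacking both classes in a repeat are skipped for that
#' repeat. Performance typically rises with the number of known targets.
#'
#' @param result a [run_repeated_cv()] result (supplies out-of-fold scores)
#' @param combos the combinations the result was computed on
#' @return data.frame: bin, n_combos, mean_auc, sd_auc, n_repeats_used.
#' @export
stratified_auc <- function(result, combos) {
  n_targets <- vapply(combos, function(cb) length(cb$drug_targets), 1L)
  names(n_targets) <- combo_ids(combos)
  bin_of <- ifelse(n_targets == 1L, "1", ifelse(n_targets == 2L, "2", ">2"))
  oof <- result$oof
  oof$bin <- bin_of[oof$combo_id]
  out <- list()
  for (b in c("1", "2", ">2")) {
    sub <- oof[oof$bin == b & !is.na(oof$bin), , drop = FALSE]
    if (!nrow(sub)) next
    aucs <- vapply(split(sub, sub$repeat_id), function(d) {
      if (length(unique(d$label)) < 2L) NA_real_ else
        100 * .auc(d$label, d$score)
    }, 0)
    used <- aucs[!is.na(aucs)]
    if (length(used) < length(aucs))
      message("stratum '", b, "': ", sum(is.na(aucs)),
              " repeat(s) lacked both classes, skipped")
    out[[b]] <- data.frame(
      bin = b, n_combos = sum(bin_of == b, na.rm = TRUE),
      mean_auc = if (length(used)) mean(used) else NA_real_,
      sd_auc = if (length(used) > 1L) stats::sd(used) else NA_real_,
      n_repeats_used = length(used), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Training-set class-ratio experiment
#'
#' For each ratio r, training folds receive r negatives per positive (the
#' balanced evaluation negatives' training share plus extra train-only
#' negatives) while the held-out folds stay balanced 1:1. Ratio 1 reproduces
#' [run_repeated_cv()] exactly under the same configuration seed.
#'
#' @param features,labels as in [run_repeated_cv()]
#' @param ratios numeric vector of training ratios (each >= 1)
#' @param config a [cv_config()]
#' @return List with `summary` (data.frame: ratio, mean_auc, sd_auc,
#'   mean_aupr, sd_aupr) and `results` (one `kg_cv_result` per ratio).
#' @export
ratio_experiment <- function(features, labels, ratios = c(1, 2, 5, 10),
                             config = cv_config()) {
  stopifnot(all(ratios >= 1))
  results <- lapply(ratios, function(r)
    .cv_engine(features, labels, config, ratio = r))
  summary <- data.frame(
    ratio = ratios,
    mean_auc = vapply(results, `[[`, 0, "mean_auc"),
    sd_auc = vapply(results, `[[`, 0, "sd_auc"),
    mean_aupr = vapply(results, `[[`, 0, "mean_aupr"),
    sd_aupr = vapply(results, `[[`, 0, "sd_aupr"))
  list(summary = summary, results = results)
}
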