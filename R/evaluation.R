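# Metrics and statistical procedures: MAE statistics, 3-class macro IoU,
# pixel accuracy, stratified k-fold construction, paired-bootstrap
# interobserver agreement, and cross-validated report tables.

#' Mean and spread of absolute errors
#'
#' @param pred,truth Equal-length numeric vectors of scores.
#' @return A list with `mean` and `sd`: the mean and the population
#'   standard deviation (divisor n) of `|pred - truth|`.
#' @export
mae_stats <- function(pred, truth) {
  if (length(pred) != length(truth))
    ep_stop("pred and truth must have equal length", "epiderm_shape_error")
  if (length(pred) < 1) ep_stop("need at least one pair", "epiderm_shape_error")
  ae <- abs(pred - truth)
  list(mean = mean(ae), sd = pop_sd(ae))
}

#' Macro-averaged intersection over union
#'
#' Per-class Jaccard index over the three classes (background, healthy
#' epidermis, damaged epidermis), averaged with equal weight. A class
#' absent from both masks scores 1.0 — so the macro average stays over
#' exactly three classes, while a spurious prediction of an absent class
#' (union > 0, intersection 0) pulls the score down sharply.
#'
#' @param pred,truth Integer label matrices with classes in `{0, 1, 2}`.
#' @return Macro IoU in `[0, 1]`.
#' @export
macro_iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    ep_stop("pred and truth must have the same shape", "epiderm_shape_error")
  ious <- vapply(0:2, function(k) {
    p <- pred == k; t <- truth == k
    u <- sum(p | t)
    if (u == 0) 1.0 else sum(p & t) / u
  }, numeric(1))
  mean(ious)
}

#' Pixel-wise accuracy
#'
#' @param pred,truth Label matrices of identical shape.
#' @return Fraction of pixels with equal labels.
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    ep_stop("pred and truth must have the same shape", "epiderm_shape_error")
  mean(pred == truth)
}

#' Stratified k-fold assignment
#'
#' Samples are grouped by the composite stratum (staining, tissue,
#' has_segmentation); within each stratum the samples are shuffled and
#' dealt round-robin, with the dealing position carried over from stratum
#' to stratum so overall fold sizes also stay within one of each other.
#'
#' @param manifest An `epiderm_manifest`.
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the within-stratum shuffles.
#' @return A list of class `epiderm_folds` with `k`, `fold_of` (named
#'   integer vector, fold index 1..k per sample id) and `strata_key`.
#' @export
stratified_folds <- function(manifest, k = 10, seed = 42L) {
  df <- as.data.frame(manifest)
  if (k < 2) ep_stop("k must be at least 2", "epiderm_config_error")
  if (k > nrow(df)) ep_stop("k exceeds the number of samples", "epiderm_config_error")
  key <- paste(df$staining, df$tissue, df$has_segmentation, sep = "|")
  fold_of <- integer(nrow(df))
  names(fold_of) <- df$sample_id
  pos <- 0L
  with_seed(seed, {
    for (s in sort(unique(key))) {
      idx <- which(key == s)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- (pos + seq_along(idx) - 1L) %% k + 1L
      pos <- (pos + length(idx)) %% k
    }
  })
  structure(list(k = as.integer(k), fold_of = fold_of,
                 strata_key = c("staining", "tissue", "has_segmentation")),
            class = "epiderm_folds")
}

#' Ids held out in / kept for training against one fold
#' @param folds An `epiderm_folds`.
#' @param fold Fold index in 1..k.
#' @return Character vector of sample ids.
#' @export
fold_test_ids <- function(folds, fold) names(folds$fold_of)[folds$fold_of == fold]

#' @rdname fold_test_ids
#' @export
fold_train_ids <- function(folds, fold) names(folds$fold_of)[folds$fold_of != fold]

#' Bootstrap distribution of agreement statistics
#'
#' Nonparametric bootstrap of the paired absolute errors between two
#' score vectors: each of `n_boot` draws resamples the n pairs with
#' replacement and recomputes [mae_stats()].
#'
#' @param scores_a,scores_b Equal-length score vectors (n >= 2).
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @param scenario Optional label stored in the result.
#' @return A list of class `epiderm_agreement` with `mae_samples`,
#'   `sd_samples` (length `n_boot`), `scenario`, `n`, `seed`.
#' @export
bootstrap_agreement <- function(scores_a, scores_b, n_boot = 1000, seed = 42L,
                                scenario = NA_character_) {
  n <- length(scores_a)
  if (length(scores_b) != n) ep_stop("score vectors differ in length",
                                     "epiderm_shape_error")
  if (n < 2) ep_stop("need at least two samples", "epiderm_shape_error")
  idx <- with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE),
                                n, n_boot))
  mae <- numeric(n_boot); sdv <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ae <- abs(scores_a[idx[, b]] - scores_b[idx[, b]])
    mae[b] <- mean(ae)
    sdv[b] <- pop_sd(ae)
  }
  structure(list(scenario = scenario, n_boot = as.integer(n_boot),
                 mae_samples = mae, sd_samples = sdv, n = n, seed = seed),
            class = "epiderm_agreement")
}

#' Human-level comparison across the three agreement scenarios
#'
#' Runs the paired bootstrap on the three scenarios used to assess
#' whether a model matches interobserver agreement: annotator 1 vs
#' annotator 2, annotator 1 vs model, annotator 2 vs model. All scenarios
#' share the same resampled index sets, so draw b of one scenario is
#' directly comparable to draw b of another; `dominance` reports, for each
#' model scenario, the fraction of paired draws in which the model's MAE
#' lies below the annotator-vs-annotator MAE.
#'
#' @param ann1,ann2,model_scores Equal-length score vectors.
#' @param n_boot Number of bootstrap draws.
#' @param seed RNG seed.
#' @return A list with the three `epiderm_agreement` objects and the
#'   `dominance` fractions.
#' @export
human_level_bootstrap <- function(ann1, ann2, model_scores, n_boot = 1000,
                                  seed = 42L) {
  n <- length(ann1)
  stopifnot(length(ann2) == n, length(model_scores) == n, n >= 2)
  idx <- with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE),
                                n, n_boot))
  stat <- function(a, b) {
    mae <- numeric(n_boot); sdv <- numeric(n_boot)
    for (bb in seq_len(n_boot)) {
      ae <- abs(a[idx[, bb]] - b[idx[, bb]])
      mae[bb] <- mean(ae); sdv[bb] <- pop_sd(ae)
    }
    list(mae = mae, sd = sdv)
  }
  aa <- stat(ann1, ann2)
  a1m <- stat(ann1, model_scores)
  a2m <- stat(ann2, model_scores)
  wrap <- function(s, lab) structure(
    list(scenario = lab, n_boot = as.integer(n_boot), mae_samples = s$mae,
         sd_samples = s$sd, n = n, seed = seed), class = "epiderm_agreement")
  list(pathologist_vs_pathologist = wrap(aa, "pathologist_vs_pathologist"),
       pathologist1_vs_model = wrap(a1m, "pathologist1_vs_model"),
       pathologist2_vs_model = wrap(a2m, "pathologist2_vs_model"),
       dominance = c(model_vs_ann1 = mean(a1m$mae < aa$mae),
                     model_vs_ann2 = mean(a2m$mae < aa$mae)))
}

#' Cross-validated evaluation report
#'
#' For every fold, trains with `trainer$fit` on the remaining samples
#' (once per repeat) and evaluates on the held-out fold, producing the
#' model-comparison table layout: MAE against S_nuclei on all evaluable
#' samples, MAE against S_area on annotated samples, and — for mask
#' producing models — macro IoU and pixel accuracy. Score estimates are
#' passed through [cross_score()] for the off-diagonal comparisons.
#' Aggregates are reported as mean and standard deviation across folds
#' (`sd_folds`, of per-fold means) and across all fold x repeat runs
#' (`sd_runs`).
#'
#' @param manifest An `epiderm_manifest`.
#' @param folds An `epiderm_folds` from [stratified_folds()].
#' @param trainer A list with `fit(manifest, train_ids, seed)` returning a
#'   model, and `predict(model, image)` returning a list with a
#'   [score_pair()] `scores` and optionally `mask`. See
#'   [segmentation_trainer()] and [regression_trainer()].
#' @param repeats Independent trainings per fold (default 1).
#' @param seed Base seed; run seeds are derived per fold and repeat.
#' @return A data.frame with one row per fold x repeat plus aggregate
#'   rows; undefined-score failures are counted in `n_flagged`.
#' @export
cross_validate_report <- function(manifest, folds, trainer, repeats = 1,
                                  seed = 42L) {
  df <- as.data.frame(manifest)
  rows <- list()
  for (f in seq_len(folds$k)) {
    train_ids <- fold_train_ids(folds, f)
    test_ids <- fold_test_ids(folds, f)
    if (length(train_ids) == 0 || length(test_ids) == 0)
      ep_stop("fold with no train or test samples", "epiderm_validation_error")
    for (r in seq_len(repeats)) {
      run_seed <- seed + 1000L * f + r
      model <- trainer$fit(manifest, train_ids, run_seed)
      pn <- c(); tn <- c(); pa <- c(); ta <- c()
      iou <- c(); acc <- c(); flagged <- 0L
      for (id in test_ids) {
        rec <- df[df$sample_id == id, , drop = FALSE]
        smp <- load_sample(rec, base_dir = attr(manifest, "base_dir"))
        pred <- tryCatch(trainer$predict(model, smp$image),
                         epiderm_undefined_score = function(e) NULL)
        if (is.null(pred)) { flagged <- flagged + 1L; next }
        pn <- c(pn, cross_score(pred$scores, "nuclei")); tn <- c(tn, rec$s_nuclei)
        if (!is.na(rec$s_area)) {
          pa <- c(pa, cross_score(pred$scores, "area")); ta <- c(ta, rec$s_area)
        }
        if (!is.null(pred$mask) && !is.null(smp$mask)) {
          iou <- c(iou, macro_iou(pred$mask, smp$mask))
          acc <- c(acc, pixel_accuracy(pred$mask, smp$mask))
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        fold = f, repeat_ = r,
        mae_s_nuclei = if (length(pn)) mae_stats(pn, tn)$mean else NA_real_,
        mae_s_area = if (length(pa)) mae_stats(pa, ta)$mean else NA_real_,
        iou_macro = if (length(iou)) mean(iou) else NA_real_,
        pixel_acc = if (length(acc)) mean(acc) else NA_real_,
        n = length(test_ids), n_flagged = flagged)
    }
  }
  per_run <- do.call(rbind, rows)
  metrics <- c("mae_s_nuclei", "mae_s_area", "iou_macro", "pixel_acc")
  per_fold <- stats::aggregate(per_run[metrics], by = list(fold = per_run$fold),
                               FUN = function(x) mean(x, na.rm = TRUE))
  agg <- function(fun) vapply(metrics, function(m) {
    v <- per_fold[[m]][is.finite(per_fold[[m]])]
    if (length(v)) fun(v) else NA_real_
  }, numeric(1))
  sd_runs <- vapply(metrics, function(m) {
    v <- per_run[[m]][is.finite(per_run[[m]])]
    if (length(v) > 1) stats::sd(v) else NA_real_
  }, numeric(1))
  summary_rows <- data.frame(
    fold = NA_integer_, repeat_ = NA_integer_, rbind(
      mean = agg(mean),
      sd_folds = agg(function(v) if (length(v) > 1) stats::sd(v) else NA_real_),
      sd_runs = sd_runs),
    n = sum(per_run$n[per_run$repeat_ == 1]), n_flagged = sum(per_run$n_flagged))
  summary_rows$aggregate <- rownames(summary_rows)
  per_run$aggregate <- NA_character_
  out <- rbind(per_run, summary_rows)
  rownames(out) <- NULL
  out
}

#' Trainer specifications for cross-validation
#'
#' `segmentation_trainer` fits one U-Net (per repeat) and scores via the
#' predicted mask; `regression_trainer` fits the (optionally masked)
#' regressor on the requested target.
#'
#' @param config Model configuration ([unet_config()] or
#'   [regressor_config()]).
#' @param target Regression target.
#' @param masker_cfg Optional [masker_config()]; when given the masked
#'   regression variant is used (the masker is trained on the same fold).
#' @return A trainer list usable with [cross_validate_report()].
#' @export
segmentation_trainer <- function(config = unet_config()) {
  list(
    fit = function(manifest, train_ids, seed) {
      cfg <- config
      cfg$seed <- as.integer(seed %% .Machine$integer.max)
      df <- as.data.frame(manifest)
      masked <- train_ids[df$has_segmentation[match(train_ids, df$sample_id)]]
      train_segmenter(manifest, masked, cfg, repeats = 1L)[[1]]
    },
    predict = function(model, image) {
      pm <- predict_mask(model, image)
      area <- s_area_from_mask(pm$mask)
      list(scores = score_pair(s_area = area$s_area), mask = pm$mask)
    })
}

#' @rdname segmentation_trainer
#' @export
regression_trainer <- function(config = regressor_config(),
                               target = c("s_nuclei", "s_area"),
                               masker_cfg = NULL) {
  target <- match.arg(target)
  list(
    fit = function(manifest, train_ids, seed) {
      cfg <- config
      cfg$seed <- as.integer(seed %% .Machine$integer.max)
      masker <- NULL
      if (!is.null(masker_cfg)) {
        mcfg <- masker_cfg
        mcfg$seed <- cfg$seed + 1L
        df <- as.data.frame(manifest)
        masked <- train_ids[df$has_segmentation[match(train_ids, df$sample_id)]]
        masker <- build_and_train_masker(manifest, masked, mcfg)
      }
      model <- train_regressor(manifest, train_ids, target, cfg, masker = masker)
      model$masker <- masker
      model
    },
    predict = function(model, image) {
      s <- predict_score(model, image, masker = model$masker)
      scores <- if (model$target == "s_nuclei") score_pair(s_nuclei = s)
                else score_pair(s_area = s)
      list(scores = scores, mask = NULL)
    })
}
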