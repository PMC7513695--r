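#' Nested cross-validated training of one classifier family
#'
#' Outer 5-fold stratified cross-validation with an inner 3-fold stratified
#' grid search maximizing AUC-ROC. Hyperparameters are tuned per outer fold
#' (true nested CV); for boosted trees the round count additionally comes
#' from early stopping against the inner validation folds. Every labeled gene
#' receives an out-of-fold risk score from the one model whose training fold
#' excluded it.
#'
#' @param features a [assemble_features()] table; only genes labeled
#'   positive/negative are used.
#' @param spec a [model_spec()].
#' @param n_folds outer folds (default 5).
#' @param inner_folds inner grid-search folds (default 3).
#' @param seed integer seed governing fold assignment and model fits.
#' @return An object of class `cv_result`: per-fold AUC-ROC / AUC-PRC, the
#'   chosen hyperparameters per fold, and the out-of-fold score table.
#' @export
run_cv <- function(features, spec, n_folds = 5L, inner_folds = 3L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- feature_xy(features)
  fold <- with_seed(derive_seed(seed, 1L),
                    stratified_folds(xy$y, n_folds))
  check_folds(xy$y, fold)

  oof <- rep(NA_real_, length(xy$y))
  fold_rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    hold <- fold == f
    tuned <- tune_grid(xy$x[!hold, , drop = FALSE], xy$y[!hold], spec,
                       inner_folds, seed = derive_seed(seed, 100L + f))
    fit <- fit_model(spec$family, xy$x[!hold, , drop = FALSE], xy$y[!hold],
                     tuned$params, seed = derive_seed(seed, 200L + f))
    scores <- predict_model(fit, xy$x[hold, , drop = FALSE])
    oof[hold] <- scores
    fold_rows[[f]] <- tibble(
      fold = f,
      auc_roc = auc_roc(scores, xy$y[hold]),
      auc_prc = auc_prc(scores, xy$y[hold]),
      params = list(tuned$params),
      inner_auc = tuned$inner_auc
    )
  }
  structure(
    list(
      family = spec$family,
      spec = spec,
      folds = bind_rows(fold_rows),
      oof = tibble(gene = xy$gene, label = xy$y, score = oof, fold = fold),
      mean_auc_roc = mean(map_dbl(fold_rows, ~ .x$auc_roc)),
      mean_auc_prc = mean(map_dbl(fold_rows, ~ .x$auc_prc)),
      seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
#' @method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean AUC-ROC %.3f, mean AUC-PRC %.3f over %d folds\n",
              x$family, x$mean_auc_roc, x$mean_auc_prc, nrow(x$folds)))
  invisible(x)
}

feature_xy <- function(features) {
  feature_names <- attr(features, "feature_names") %||%
    setdiff(names(features), c("gene", "label", "network_provenance"))
  labeled <- features$label %in% c("positive", "negative")
  x <- as.matrix(features[labeled, feature_names, drop = FALSE])
  rownames(x) <- features$gene[labeled]
  list(x = x, y = features$label[labeled] == "positive",
       gene = features$gene[labeled], feature_names = feature_names)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

check_folds <- function(y, fold) {
  for (f in unique(fold)) {
    for (part in list(fold == f, fold != f)) {
      if (length(unique(y[part])) < 2) {
        abort("A fold would contain a single class; reduce `n_folds` or relabel.")
      }
    }
  }
}

tune_grid <- function(x, y, spec, inner_folds, seed) {
  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  ifold <- with_seed(seed, stratified_folds(y, inner_folds))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, , drop = FALSE])
    params$max_rounds <- spec$max_rounds
    aucs <- numeric(inner_folds)
    rounds <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      hold <- ifold == f
      valid <- if (spec$family == "gradient_boosted_trees") {
        list(x = x[hold, , drop = FALSE], y = y[hold])
      }
      fit <- fit_model(spec$family, x[!hold, , drop = FALSE], y[!hold],
                       params, seed = derive_seed(seed, 10L + f),
                       valid = valid)
      aucs[f] <- auc_roc(predict_model(fit, x[hold, , drop = FALSE]), y[hold])
      rounds[f] <- fit$best_iteration %||% NA_real_
    }
    mean_auc <- mean(aucs)
    if (is.null(best) || mean_auc > best$inner_auc + 1e-12) {
      chosen <- params
      if (spec$family == "gradient_boosted_trees") {
        chosen$nrounds <- max(1L, as.integer(round(mean(rounds, na.rm = TRUE))))
      }
      best <- list(params = chosen, inner_auc = mean_auc)
    }
  }
  best
}

#' Pick the winning classifier family
#'
#' Argmax of mean outer-fold AUC-ROC; ties broken by mean AUC-PRC, then by
#' the fixed family order (logistic regression, Gaussian SVM, random forest,
#' gradient boosted trees).
#'
#' @param cv_results list of [run_cv()] results (named or not).
#' @return The winning `cv_result`.
#' @export
select_model <- function(cv_results) {
  if (inherits(cv_results, "cv_result")) cv_results <- list(cv_results)
  if (length(cv_results) == 0) abort("Need at least one CV result.")
  fam <- map_chr(cv_results, "family")
  roc <- map_dbl(cv_results, "mean_auc_roc")
  prc <- map_dbl(cv_results, "mean_auc_prc")
  ord <- order(-roc, -prc, match(fam, model_families))
  cv_results[[ord[1]]]
}

#' Fit the final model and score the genome
#'
#' Re-tunes the winning family's hyperparameters by an inner grid search on
#' all labeled genes, fits the final model on them, and scores every
#' unlabeled gene. Labeled genes keep their out-of-fold scores (each produced
#' by the model that excluded the gene), so no gene is scored by a model that
#' saw it. The combined table is ranked jointly (rank 1 = highest score),
#' cut into deciles, and classified at the F1-optimal (or a fixed) threshold.
#'
#' @param features full [assemble_features()] table (labeled + unlabeled).
#' @param cv_result the winning family's [run_cv()] result.
#' @param threshold `"f1_auto"` (default) to maximize F1 on the out-of-fold
#'   scores, or a fixed numeric threshold.
#' @param inner_folds folds for the final hyperparameter search.
#' @param seed integer seed.
#' @return An object of class `risk_model`: `scores` (gene, score, rank,
#'   decile, source, predicted_class), `threshold`, `f1`, `importance`,
#'   `family`, and the tuned `params`.
#' @export
fit_final_and_score <- function(features, cv_result, threshold = "f1_auto",
                                inner_folds = 3L, seed = 1L) {
  stopifnot(inherits(cv_result, "cv_result"))
  xy <- feature_xy(features)
  spec <- cv_result$spec
  tuned <- tune_grid(xy$x, xy$y, spec, inner_folds,
                     seed = derive_seed(seed, 300L))
  params <- tuned$params
  if (spec$family == "gradient_boosted_trees" && is.null(params$nrounds)) {
    params$nrounds <- 100L
  }
  fit <- fit_model(spec$family, xy$x, xy$y, params,
                   seed = derive_seed(seed, 301L))

  feature_names <- xy$feature_names
  unlabeled <- features$label == "unlabeled"
  scored <- cv_result$oof |>
    select("gene", "score") |>
    mutate(source = "out_of_fold")
  if (any(unlabeled)) {
    xu <- as.matrix(features[unlabeled, feature_names, drop = FALSE])
    rownames(xu) <- features$gene[unlabeled]
    scored <- bind_rows(scored, tibble(
      gene = features$gene[unlabeled],
      score = predict_model(fit, xu),
      source = "final_model"
    ))
  }

  if (identical(threshold, "f1_auto")) {
    thr <- select_threshold_f1(cv_result$oof$score, cv_result$oof$label)
  } else {
    assert_number(threshold, "threshold")
    pred <- cv_result$oof$score >= threshold
    thr <- list(threshold = threshold,
                f1 = f1_at(pred, cv_result$oof$label))
  }

  n <- nrow(scored)
  scores <- scored |>
    mutate(rank = score_ranks(.data$score, .data$gene),
           decile = rank_decile(.data$rank, n),
           predicted_class = ifelse(.data$score >= thr$threshold,
                                    "risk", "non_risk")) |>
    arrange(.data$rank) |>
    relocate("gene", "score", "rank", "decile", "source", "predicted_class")

  structure(
    list(scores = scores, threshold = thr$threshold, f1 = thr$f1,
         importance = model_importance(fit), family = spec$family,
         params = params, seed = seed),
    class = "risk_model"
  )
}

#' @export
#' @method print risk_model
print.risk_model <- function(x, ...) {
  cat(sprintf(
    "<risk_model> %s: %d genes scored, threshold %.3f (F1 %.3f), %d predicted risk\n",
    x$family, nrow(x$scores), x$threshold, x$f1,
    sum(x$scores$predicted_class == "risk")
  ))
  invisible(x)
}
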