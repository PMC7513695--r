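test_that("a perfectly separating feature yields mean AUC-ROC of 1", {
  ft <- toy_feature_table(n = 90, p = 4, signal = 0, seed = 2)
  ft$f1 <- ifelse(ft$label == "positive", 1, 0) + seq_len(nrow(ft)) * 1e-6
  cv <- run_cv(ft, model_spec("logistic_regression", grid = list(lambda = 0.1)),
               seed = 1)
  expect_equal(cv$mean_auc_roc, 1.0)
  expect_equal(cv$mean_auc_prc, 1.0)
})

test_that("the out-of-fold contract holds for every family", {
  ft <- toy_feature_table(n = 60, p = 5, seed = 3)
  for (fam in c("logistic_regression", "svm_gaussian", "random_forest",
                "gradient_boosted_trees")) {
    grid <- switch(fam,
                   logistic_regression = list(lambda = 0.1),
                   svm_gaussian = list(gamma_mult = 1, cost = 1),
                   random_forest = list(num_trees = 50, mtry_frac = 0.3),
                   gradient_boosted_trees = list(max_depth = 3, eta = 0.1))
    cv <- run_cv(ft, model_spec(fam, grid = grid, max_rounds = 30), seed = 4)
    # every labeled gene in exactly one hold-out fold, scored there
    expect_setequal(cv$oof$gene, ft$gene[ft$label != "unlabeled"])
    expect_false(anyNA(cv$oof$score))
    expect_true(all(cv$oof$score >= 0 & cv$oof$score <= 1))
    expect_equal(sort(unique(cv$oof$fold)), 1:5)
    expect_true(all(cv$folds$auc_roc >= 0 & cv$folds$auc_roc <= 1))
  }
})

test_that("CV is deterministic in the seed", {
  ft <- toy_feature_table(n = 60, p = 5, seed = 3)
  spec <- model_spec("gradient_boosted_trees",
                     grid = list(max_depth = 3, eta = 0.1), max_rounds = 30)
  cv1 <- run_cv(ft, spec, seed = 7)
  cv2 <- run_cv(ft, spec, seed = 7)
  expect_identical(cv1$oof$score, cv2$oof$score)
  cv3 <- run_cv(ft, spec, seed = 8)
  expect_false(identical(cv1$oof$score, cv3$oof$score))
})

test_that("tree-family CV is invariant to monotone feature transforms", {
  ft <- toy_feature_table(n = 60, p = 5, seed = 9)
  spec <- model_spec("gradient_boosted_trees",
                     grid = list(max_depth = 3, eta = 0.1), max_rounds = 30)
  cv1 <- run_cv(ft, spec, seed = 5)
  ft2 <- ft
  for (f in attr(ft, "feature_names")) ft2[[f]] <- exp(ft2[[f]] / 2)
  cv2 <- run_cv(ft2, spec, seed = 5)
  expect_equal(cv1$folds$auc_roc, cv2$folds$auc_roc, tolerance = 1e-9)
})

test_that("model selection maximizes AUC-ROC with documented tie-breaks", {
  fake <- function(family, roc, prc) {
    structure(list(family = family, mean_auc_roc = roc, mean_auc_prc = prc),
              class = "cv_result")
  }
  a <- fake("logistic_regression", 0.9, 0.5)
  b <- fake("gradient_boosted_trees", 0.8, 0.9)
  expect_equal(select_model(list(a, b))$family, "logistic_regression")
  # tie on AUC-ROC: higher AUC-PRC wins
  b2 <- fake("gradient_boosted_trees", 0.9, 0.9)
  expect_equal(select_model(list(a, b2))$family, "gradient_boosted_trees")
  # full tie: fixed family order
  b3 <- fake("gradient_boosted_trees", 0.9, 0.5)
  expect_equal(select_model(list(b3, a))$family, "logistic_regression")
  # single candidate
  expect_equal(select_model(list(b))$family, "gradient_boosted_trees")
})

test_that("single-class folds are rejected before any fitting", {
  ft <- toy_feature_table(n = 30, p = 3, seed = 1)
  ft$label[ft$label == "positive"] <- "negative"
  ft$label[1] <- "positive"  # one positive cannot stratify over 5 folds
  expect_error(run_cv(ft, model_spec("logistic_regression")), "single class")
})

test_that("final scoring ranks jointly, flags sources, applies the threshold", {
  ft <- toy_feature_table(n = 150, p = 6, signal = 2, seed = 10)
  ft$label[101:150] <- "unlabeled"
  attr(ft, "feature_names") <- paste0("f", 1:6)
  cv <- run_cv(ft, model_spec("gradient_boosted_trees",
                              grid = list(max_depth = 3, eta = 0.1),
                              max_rounds = 40), seed = 2)
  rm <- fit_final_and_score(ft, cv, seed = 2)
  sc <- rm$scores

  expect_setequal(sc$gene, ft$gene)
  expect_setequal(sc$rank, seq_len(nrow(sc)))
  expect_equal(sc$decile[sc$rank == 1], 1L)
  expect_equal(sum(sc$decile == 1), ceiling(nrow(sc) / 10))
  expect_equal(sc$source[match(ft$gene[1], sc$gene)], "out_of_fold")
  expect_equal(sc$source[match(ft$gene[150], sc$gene)], "final_model")
  expect_true(all(sc$predicted_class[sc$score >= rm$threshold] == "risk"))
  # labeled genes keep their out-of-fold scores untouched
  expect_equal(sc$score[match(cv$oof$gene, sc$gene)], cv$oof$score)

  # duplicated unlabeled feature row scores identically under the same model
  ft_dup <- dplyr::bind_rows(ft, dplyr::mutate(ft[150, ], gene = "G_DUP"))
  attr(ft_dup, "feature_names") <- paste0("f", 1:6)
  class(ft_dup) <- class(ft)
  rm2 <- fit_final_and_score(ft_dup, cv, seed = 2)
  expect_equal(rm2$scores$score[rm2$scores$gene == "G_DUP"],
               rm2$scores$score[rm2$scores$gene == ft$gene[150]])

  # fixed threshold policy
  rm3 <- fit_final_and_score(ft, cv, threshold = 0.5, seed = 2)
  expect_equal(rm3$threshold, 0.5)

  # importance is reported with its method flagged
  expect_true(all(c("feature", "importance", "method") %in% names(rm$importance)))
  expect_equal(unique(rm$importance$method), "average_gain")
})

test_that("feature-name mismatch between fit and predict is an error", {
  ft <- toy_feature_table(n = 60, p = 4, seed = 11)
  cv <- run_cv(ft, model_spec("logistic_regression", grid = list(lambda = 0.1)),
               seed = 1)
  # a recorded feature missing from the table at predict time must fail loudly
  ft_bad <- ft
  ft_bad$f1 <- NULL
  attr(ft_bad, "feature_names") <- attr(ft, "feature_names")
  ft_bad$label[1:10] <- "unlabeled"
  expect_error(fit_final_and_score(ft_bad, cv, seed = 1))
})
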