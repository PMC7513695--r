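model_families <- c("logistic_regression", "svm_gaussian", "random_forest",
                    "gradient_boosted_trees")

#' Specify a classifier family and its hyperparameter grid
#'
#' The four supported families are L2-regularized logistic regression
#' (glmnet), a Gaussian-kernel SVM (e1071), a probability random forest
#' (ranger), and gradient boosted trees (xgboost). Omitted grid entries fall
#' back to documented defaults; for boosted trees the number of rounds is not
#' part of the grid but chosen by early stopping against the inner validation
#' fold (capped at `max_rounds`).
#'
#' @param family one of `"logistic_regression"`, `"svm_gaussian"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`.
#' @param grid named list of hyperparameter value vectors, crossed during the
#'   inner grid search.
#' @param max_rounds boosting-round cap (boosted trees only).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = model_families, grid = NULL, max_rounds = 500L) {
  family <- match.arg(family)
  default <- switch(family,
    logistic_regression = list(lambda = c(0.01, 0.1, 1, 10)),
    svm_gaussian = list(gamma_mult = c(0.5, 1, 2), cost = c(0.1, 1, 10)),
    random_forest = list(num_trees = 500, mtry_frac = c(NA, 0.3)),
    gradient_boosted_trees = list(max_depth = c(3, 4, 6), eta = c(0.05, 0.1))
  )
  grid <- modifyList(default, grid %||% list())
  if (any(lengths(grid) == 0)) abort("Every grid entry needs at least one value.")
  structure(list(family = family, grid = grid,
                 max_rounds = as.integer(max_rounds)),
            class = "model_spec")
}

# ---- internal fit/predict dispatch ----------------------------------------
# x: numeric matrix (genes x features); y: logical positive indicator.
# Linear and kernel models are standardized with training-fold statistics;
# tree families consume raw features.

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  list(mu = mu, sigma = sigma)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$mu), 2, std$sigma, "/")
}

fit_model <- function(family, x, y, params, seed = 1L, valid = NULL) {
  obj <- list(family = family, params = params, features = colnames(x))
  if (family %in% c("logistic_regression", "svm_gaussian")) {
    obj$std <- standardize_fit(x)
    x <- standardize_apply(x, obj$std)
  }
  obj$fit <- switch(family,
    logistic_regression = glmnet::glmnet(
      x, factor(y, levels = c(FALSE, TRUE)), family = "binomial",
      alpha = 0, lambda = params$lambda, standardize = FALSE
    ),
    svm_gaussian = with_seed(seed, e1071::svm(
      x, factor(y, levels = c(FALSE, TRUE)),
      kernel = "radial", gamma = params$gamma_mult / ncol(x),
      cost = params$cost, scale = FALSE
    )),
    random_forest = {
      mtry <- if (is.na(params$mtry_frac)) {
        floor(sqrt(ncol(x)))
      } else {
        max(1L, floor(params$mtry_frac * ncol(x)))
      }
      ranger::ranger(
        x = x, y = factor(y, levels = c(FALSE, TRUE)),
        num.trees = params$num_trees, mtry = mtry, probability = TRUE,
        importance = "impurity", seed = seed, num.threads = 1
      )
    },
    gradient_boosted_trees = fit_xgb(x, y, params, seed, valid)
  )
  if (family == "gradient_boosted_trees") {
    obj$best_iteration <- attr(obj$fit, "chosen_rounds")
  }
  obj
}

fit_xgb <- function(x, y, params, seed, valid) {
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
  xgb_params <- list(objective = "binary:logistic", eval_metric = "auc",
                     max_depth = params$max_depth, eta = params$eta,
                     nthread = 1, seed = seed)
  if (!is.null(valid)) {
    dvalid <- xgboost::xgb.DMatrix(valid$x, label = as.numeric(valid$y))
    fit <- xgboost::xgb.train(
      params = xgb_params, data = dtrain,
      nrounds = params$max_rounds %||% 500L,
      evals = list(valid = dvalid),
      early_stopping_rounds = 20L, verbose = 0
    )
    attr(fit, "chosen_rounds") <-
      as.integer(xgboost::xgb.attributes(fit)$best_iteration)
  } else {
    fit <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                              nrounds = params$nrounds, verbose = 0)
    attr(fit, "chosen_rounds") <- as.integer(params$nrounds)
  }
  fit
}

predict_model <- function(obj, x) {
  x <- x[, obj$features, drop = FALSE]
  if (!is.null(obj$std)) x <- standardize_apply(x, obj$std)
  switch(obj$family,
    logistic_regression = as.numeric(
      predict(obj$fit, x, type = "response", s = obj$params$lambda)
    ),
    svm_gaussian = {
      # decision values mapped through plogis so scores live in [0, 1];
      # orientation fixed to the positive (TRUE) class
      dv <- attr(predict(obj$fit, x, decision.values = TRUE),
                 "decision.values")
      sign <- if (grepl("^TRUE", colnames(dv)[1])) 1 else -1
      as.numeric(stats::plogis(sign * dv[, 1]))
    },
    random_forest = as.numeric(predict(obj$fit, data = x)$predictions[, "TRUE"]),
    gradient_boosted_trees = {
      # iterationrange is base-1 and inclusive of both ends
      ntree <- obj$best_iteration
      rng <- if (!is.null(ntree) && length(ntree) == 1 && is.finite(ntree)) {
        c(1L, max(1L, as.integer(ntree)))
      }
      as.numeric(predict(obj$fit, xgboost::xgb.DMatrix(x),
                         iterationrange = rng))
    }
  )
}

model_importance <- function(obj) {
  switch(obj$family,
    gradient_boosted_trees = {
      imp <- xgboost::xgb.importance(model = obj$fit)
      tibble(feature = imp$Feature, importance = imp$Gain,
             method = "average_gain")
    },
    random_forest = {
      imp <- obj$fit$variable.importance
      if (is.null(imp)) {
        return(tibble(feature = obj$features, importance = NA_real_,
                      method = "unavailable"))
      }
      tibble(feature = names(imp), importance = as.numeric(imp),
             method = "impurity") |> arrange(desc(.data$importance))
    },
    logistic_regression = {
      co <- as.matrix(stats::coef(obj$fit, s = obj$params$lambda))[-1, 1]
      tibble(feature = names(co), importance = abs(co),
             method = "abs_std_coefficient") |>
        arrange(desc(.data$importance))
    },
    svm_gaussian = tibble(feature = obj$features, importance = NA_real_,
                          method = "unavailable")
  )
}
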