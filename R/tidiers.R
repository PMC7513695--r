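# broom-style accessors for the package's fitted/result objects

#' @export
tidy.cv_result <- function(x, ...) {
  x$folds |>
    mutate(family = x$family) |>
    relocate("family")
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(family = x$family,
         mean_auc_roc = x$mean_auc_roc,
         sd_auc_roc = sd(x$folds$auc_roc),
         mean_auc_prc = x$mean_auc_prc,
         sd_auc_prc = sd(x$folds$auc_prc),
         n_folds = nrow(x$folds),
         seed = x$seed)
}

#' @export
tidy.risk_model <- function(x, ...) x$scores

#' @export
glance.risk_model <- function(x, ...) {
  tibble(family = x$family, threshold = x$threshold, f1 = x$f1,
         n_genes = nrow(x$scores),
         n_predicted_risk = sum(x$scores$predicted_class == "risk"))
}

#' @export
tidy.dge_enrichment <- function(x, ...) glance.dge_enrichment(x, ...)

#' @export
glance.dge_enrichment <- function(x, ...) {
  tibble(phenotype = x$phenotype, direction = x$direction,
         observed_count = x$observed_count, null_mean = x$null_mean,
         null_sd = x$null_sd, fold = x$fold, empirical_p = x$empirical_p,
         n_perm = x$n_perm, test_set_size = x$test_set_size)
}

#' @export
tidy.go_term_clustering <- function(x, ...) {
  tibble(term = names(x$clusters), cluster = unname(x$clusters))
}
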