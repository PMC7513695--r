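#' Build a pipeline configuration
#'
#' Single-object configuration for [run_pipeline()]. Either a synthetic
#' dataset is generated in place (`synthetic = synthetic_config(...)`) or the
#' input files are read from `inputs` (paths to expression/metadata/
#' constraint/ppi/labels TSVs, DGE tables, validation lists, and a GMT file).
#' One global seed fans out to fixed per-stage sub-seeds so stage-level
#' reruns are stable.
#'
#' @param out_dir output directory.
#' @param seed global integer seed, recorded in every output.
#' @param synthetic a [synthetic_config()], or `NULL` when reading `inputs`.
#' @param inputs named list of input paths (ignored when `synthetic` given):
#'   `expression`, `sample_meta`, `constraint`, `ppi_edges`, `labels`,
#'   `dge_tables` (named vector), `validation_lists` (named vector),
#'   `go_sets`.
#' @param families classifier families to cross-validate.
#' @param threshold `"f1_auto"` or a fixed numeric risk-score threshold.
#' @param impute_k neighbours for network-feature imputation.
#' @param n_perm permutations for the DGE enrichment stage.
#' @param decile_p0 expected first-decile proportion for the binomial test.
#' @param run_validation,run_go stage toggles.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            inputs = NULL,
                            families = model_families,
                            threshold = "f1_auto",
                            impute_k = 5L,
                            n_perm = 10000L,
                            decile_p0 = 0.166,
                            run_validation = TRUE,
                            run_go = TRUE) {
  families <- match.arg(families, model_families, several.ok = TRUE)
  if (is.null(synthetic) && is.null(inputs)) {
    abort("Provide either `synthetic` or `inputs`.")
  }
  structure(
    list(out_dir = out_dir, seed = assert_count(seed, "seed", min = 0L),
         synthetic = synthetic, inputs = inputs, families = families,
         threshold = threshold, impute_k = assert_count(impute_k, "impute_k"),
         n_perm = assert_count(n_perm, "n_perm"),
         decile_p0 = assert_prob(decile_p0, "decile_p0"),
         run_validation = isTRUE(run_validation), run_go = isTRUE(run_go)),
    class = "pipeline_config"
  )
}

#' Read pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (a `synthetic:` block is passed to [synthetic_config()]).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic$seed <- y$synthetic$seed %||% y$seed %||% 1L
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  do.call(pipeline_config, y)
}

#' Run the full risk-gene ranking pipeline
#'
#' Orchestrates simulate/ingest, log transform, network construction and
#' topology features, feature assembly, nested-CV model training and
#' selection, genome-wide scoring with an F1-optimal threshold, the DGE /
#' first-decile / ranking-comparison validation statistics, and GO
#' enrichment with term clustering. Every stage writes its result under
#' `config$out_dir` in a documented text format, and a JSON run manifest
#' records seeds, per-stage wall-clock, and output checksums; identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return A list of class `pipeline_result` with the fitted objects,
#'   validation/GO results, and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  t_all <- Sys.time()
  log_stage <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  timed <- function(stage, code) {
    t0 <- Sys.time()
    res <- force(code)
    manifest$stages[[stage]] <<- list(
      status = "completed",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    )
    res
  }

  # ---- stage: data ---------------------------------------------------------
  ds <- timed("data", {
    if (!is.null(config$synthetic)) {
      log_stage("data", "generating synthetic dataset")
      generate_dataset(config$synthetic)
    } else {
      log_stage("data", "reading input files")
      read_inputs(config$inputs)
    }
  })

  # ---- stage: features -----------------------------------------------------
  features <- timed("features", {
    log_stage("features", "network topology + feature assembly")
    expr_log <- log_transform(ds$expression)
    net <- build_network(ds$ppi_edges, expr_log)
    net_feats <- topology_features(net)
    assemble_features(expr_log, net_feats, ds$constraint, ds$labels,
                      impute_k = config$impute_k)
  })

  # ---- stage: training -----------------------------------------------------
  cv_results <- timed("training", {
    lapply(setNames(config$families, config$families), function(fam) {
      log_stage("training", paste("nested CV:", fam))
      run_cv(features, model_spec(fam), seed = derive_seed(config$seed, 20L))
    })
  })
  winner <- select_model(cv_results)
  log_stage("training", sprintf("selected %s (AUC-ROC %.3f)",
                                winner$family, winner$mean_auc_roc))

  model <- timed("scoring", {
    fit_final_and_score(features, winner, threshold = config$threshold,
                        seed = derive_seed(config$seed, 30L))
  })
  scores_path <- file.path(config$out_dir, "scores.tsv")
  readr::write_tsv(model$scores, scores_path, progress = FALSE)
  readr::write_tsv(model$importance,
                   file.path(config$out_dir, "importance.tsv"),
                   progress = FALSE)
  cv_summary <- bind_rows(lapply(cv_results, glance))
  readr::write_tsv(cv_summary, file.path(config$out_dir, "cv_summary.tsv"),
                   progress = FALSE)

  # ---- stage: validation ---------------------------------------------------
  validation <- NULL
  if (config$run_validation && length(ds$dge_tables)) {
    validation <- timed("validation", {
      log_stage("validation", "DGE, decile and ranking-comparison statistics")
      risk_set <- model$scores$gene[model$scores$predicted_class == "risk"]
      dge <- imap(ds$dge_tables, function(tab, ph) {
        dge_enrichment(intersect(risk_set, tab$gene), tab,
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, 40L),
                       phenotype = ph)
      })
      decile <- bind_rows(imap(ds$validation_lists, function(genes, nm) {
        decile_enrichment(model$scores, genes, p0 = config$decile_p0,
                          list_name = nm)
      }))
      pli <- ds$constraint |>
        select(gene = "gene", score = "pLI")
      ranking <- compare_rankings(
        list(generisk = model$scores, pli = pli),
        unique(unlist(ds$validation_lists))
      )
      list(dge = dge, decile = decile, ranking = ranking)
    })
    readr::write_tsv(bind_rows(lapply(validation$dge, glance)),
                     file.path(config$out_dir, "dge_enrichment.tsv"),
                     progress = FALSE)
    readr::write_tsv(validation$decile,
                     file.path(config$out_dir, "decile_enrichment.tsv"),
                     progress = FALSE)
    readr::write_tsv(validation$ranking,
                     file.path(config$out_dir, "ranking_comparison.tsv"),
                     progress = FALSE)
  } else {
    manifest$stages[["validation"]] <- list(status = "skipped")
  }

  # ---- stage: GO enrichment ------------------------------------------------
  go <- NULL
  if (config$run_go && length(ds$go_sets)) {
    go <- timed("go", {
      log_stage("go", "GO enrichment + clustering")
      risk_set <- model$scores$gene[model$scores$predicted_class == "risk"]
      nonrisk_set <- setdiff(model$scores$gene, risk_set)
      res <- go_enrichment(risk_set, nonrisk_set, ds$go_sets)
      sig <- res$term[res$p_adj < 0.05]
      clustering <- if (length(sig) >= 2) {
        cluster_go_terms(sig, ds$go_sets, k = 5L)
      }
      list(result = res, clustering = clustering)
    })
    readr::write_tsv(go$result, file.path(config$out_dir, "go_enrichment.tsv"),
                     progress = FALSE)
    if (!is.null(go$clustering)) {
      readr::write_tsv(
        tibble(term = names(go$clustering$clusters),
               cluster = unname(go$clustering$clusters)),
        file.path(config$out_dir, "go_clusters.tsv"), progress = FALSE)
    }
  } else {
    manifest$stages[["go"]] <- list(status = "skipped")
  }

  # ---- manifest ------------------------------------------------------------
  outputs <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$config_hash <- config_hash(config)
  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  manifest$total_seconds <- round(
    as.numeric(difftime(Sys.time(), t_all, units = "secs")), 3)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(config = config, dataset = ds, features = features,
         cv_results = cv_results, model = model, validation = validation,
         go = go, manifest = manifest),
    class = "pipeline_result"
  )
}

read_inputs <- function(inputs) {
  required <- c("expression", "sample_meta", "constraint", "ppi_edges", "labels")
  missing_in <- setdiff(required, names(inputs))
  if (length(missing_in)) {
    abort(sprintf("`inputs` missing: %s", paste(missing_in, collapse = ", ")))
  }
  dge_tables <- lapply(inputs$dge_tables %||% character(), read_dge_table)
  validation_lists <- lapply(inputs$validation_lists %||% character(),
                             read_gene_list)
  list(
    expression = read_expression(inputs$expression, inputs$sample_meta),
    constraint = read_constraint(inputs$constraint),
    ppi_edges = read_ppi_edges(inputs$ppi_edges),
    labels = read_labels(inputs$labels),
    dge_tables = dge_tables,
    validation_lists = validation_lists,
    go_sets = if (!is.null(inputs$go_sets)) read_gmt(inputs$go_sets) else list(),
    truth = NULL
  )
}

# stable hash of the configuration (file paths excluded from out_dir identity)
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
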