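test_that("generation is deterministic in the seed and books are exact", {
  cfg <- tiny_config(seed = 42)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1, ds2)
  expect_false(identical(ds1$expression$values,
                         generate_dataset(tiny_config(seed = 43))$expression$values))

  counts <- table(ds1$labels$label)
  expect_equal(unname(counts[["positive"]]), cfg$n_positive)
  expect_equal(unname(counts[["negative"]]), cfg$n_negative)
  expect_equal(length(ds1$go_sets), cfg$go_n_terms)
  expect_true(all(lengths(ds1$go_sets) >= 20))
  expect_equal(length(ds1$validation_lists$proband), cfg$n_proband)

  genes <- rownames(ds1$expression$values)
  expect_true(all(c(ds1$ppi_edges$gene_a, ds1$ppi_edges$gene_b) %in% genes))
  expect_true(all(unlist(ds1$go_sets) %in% genes))
  expect_true(all(ds1$dge_tables$asd$gene %in% genes))
  expect_true(all(ds1$expression$values >= 0))

  # training positives are excluded from the validation lists
  positives <- ds1$labels$gene[ds1$labels$label == "positive"]
  expect_length(intersect(ds1$validation_lists$proband, positives), 0)
})

test_that("generator leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_dataset(tiny_config(seed = 5)))
  expect_identical(before, .Random.seed)
})

test_that("config invariants are enforced with the field named", {
  expect_error(synthetic_config(n_positive = 1500, n_negative = 1000),
               "n_positive")
  expect_error(synthetic_config(dge_down_fraction = 1.4), "dge_down_fraction")
  expect_error(synthetic_config(n_genes = 0), "n_genes")
  expect_error(synthetic_config(go_planted_terms = 99, go_n_terms = 10),
               "go_planted_terms")
})

test_that("with zero planted effects group comparisons are null-calibrated", {
  pvals <- vapply(1:200, function(s) {
    cfg <- synthetic_config(
      n_genes = 100, n_positive = 20, n_negative = 60, n_hidden_risk = 5,
      n_regions = 2, n_stages = 2, expr_effect_prenatal = 0,
      expr_effect_postnatal = 0, constraint_shift = 0,
      go_n_terms = 1, go_planted_terms = 0, n_proband = 5, n_sibling = 5,
      seed = s)
    ds <- generate_dataset(cfg)
    pos <- ds$labels$gene[ds$labels$label == "positive"]
    neg <- ds$labels$gene[ds$labels$label == "negative"]
    x <- ds$constraint$mis_z[match(pos, ds$constraint$gene)]
    y <- ds$constraint$mis_z[match(neg, ds$constraint$gene)]
    stats::wilcox.test(x, y)$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted prenatal expression shift is recovered and monotone", {
  recover_p <- function(shift, seed = 7) {
    ds <- generate_dataset(tiny_config(seed = seed,
                                       expr_effect_prenatal = shift,
                                       expr_effect_postnatal = 0))
    meta <- ds$expression$sample_meta
    vals <- log2(ds$expression$values + 1)
    prenatal_mean <- rowMeans(vals[, meta$prenatal, drop = FALSE])
    # within-gene prenatal-vs-postnatal contrast removes the gene baseline
    contrast <- prenatal_mean - rowMeans(vals[, !meta$prenatal, drop = FALSE])
    pos <- ds$labels$label == "positive"
    neg <- ds$labels$label == "negative"
    list(
      p = stats::wilcox.test(prenatal_mean[pos], prenatal_mean[neg],
                             alternative = "greater")$p.value,
      delta = mean(contrast[pos]) - mean(contrast[neg])
    )
  }
  strong <- recover_p(1.0)
  weak <- recover_p(0.3)
  none <- recover_p(0)
  expect_lt(strong$p, 0.01)
  expect_gt(strong$delta, weak$delta)
  expect_gt(weak$delta, none$delta)
})

test_that("constraint shifts follow the planted directions", {
  ds <- tiny_dataset()
  ft <- ds$constraint |>
    dplyr::left_join(ds$labels, by = "gene") |>
    dplyr::mutate(label = factor(label))
  expect_direction <- function(feature, higher_in_positives) {
    res <- compare_groups(ft, feature)
    expect_lt(res$p_value, 0.01)
    if (higher_in_positives) {
      expect_gt(res$median_1, res$median_2)
    } else {
      expect_lt(res$median_1, res$median_2)
    }
  }
  expect_direction("pLI", TRUE)
  expect_direction("mis_z", TRUE)
  expect_direction("lof_z", TRUE)
  expect_direction("pNull", FALSE)
  expect_direction("bp", TRUE)
  expect_direction("n_lof", FALSE)
  # no signal planted in syn_z
  expect_gt(compare_groups(ft, "syn_z")$p_value, 0.01)
})

test_that("planted GO terms realize the target odds ratio within 10%", {
  ds <- tiny_dataset()
  risk <- ds$truth$risk_genes
  nonrisk <- setdiff(ds$labels$gene, risk)
  target <- ds$truth$config$go_planted_or
  for (term in ds$truth$planted_go_terms) {
    set <- ds$go_sets[[term]]
    a <- length(intersect(set, risk))
    c_ <- length(intersect(set, nonrisk))
    or <- (a / (length(risk) - a)) / (c_ / (length(nonrisk) - c_))
    expect_gt(or, target * 0.9)
    expect_lt(or, target * 1.1)
  }
})

test_that("generate_dge_table plants rates, folds and sign structure", {
  labels <- tibble::tibble(gene = sprintf("G%05d", 1:20000),
                           is_risk = rep(c(TRUE, FALSE), c(2000, 18000)))
  tab <- generate_dge_table(labels, rate_bg = 0.05, rate_risk = 0.10,
                            down_fraction = 0.8, seed = 21)
  expect_equal(nrow(tab), 20000)
  # background significance rate ~ 0.05 (binomial tolerance, 4 sd)
  bg_rate <- mean(tab$p[!labels$is_risk] < 0.05)
  expect_lt(abs(bg_rate - 0.05), 4 * sqrt(0.05 * 0.95 / 18000))
  # planted enrichment fold ~ rate_risk / rate_bg = 2
  fold <- mean(tab$p[labels$is_risk] < 0.05) / bg_rate
  expect_gt(fold, 1.7)
  expect_lt(fold, 2.3)

  # equal rates: overall significant fraction ~ rate
  flat <- generate_dge_table(labels, 0.05, 0.05, 0.5, seed = 22)
  expect_lt(abs(mean(flat$p < 0.05) - 0.05), 4 * sqrt(0.05 * 0.95 / 20000))

  # degenerate: every significant risk gene down-expressed
  down <- generate_dge_table(labels, 0.05, 0.2, 1, seed = 23)
  sig_risk <- labels$is_risk & down$p < 0.05
  expect_true(all(down$beta[sig_risk] < 0))

  expect_error(generate_dge_table(labels[0, ], 0.05, 0.1, 0.5, 1), "gene")
  expect_error(generate_dge_table(labels, 1.5, 0.1, 0.5, 1), "rate_bg")
})

test_that("written datasets round-trip through the ingestion functions", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expr <- read_expression(paths["expression"], paths["sample_meta"])
  expect_equal(expr$values, ds$expression$values)
  expect_equal(expr$sample_meta$region, ds$expression$sample_meta$region)
  constr <- read_constraint(paths["constraint"])
  expect_equal(constr$gene, ds$constraint$gene)
  for (cn in setdiff(names(constr), "gene")) {
    expect_equal(as.numeric(constr[[cn]]), as.numeric(ds$constraint[[cn]]))
  }
  expect_equal(read_labels(paths["labels"]), ds$labels)
  expect_equal(as.data.frame(read_ppi_edges(paths["ppi_edges"])),
               as.data.frame(ds$ppi_edges))
  gmt <- read_gmt(paths["go_sets"])
  expect_equal(gmt, ds$go_sets)
  expect_equal(read_dge_table(file.path(dir, "dge_asd.tsv")),
               ds$dge_tables$asd)
  expect_equal(read_gene_list(file.path(dir, "list_proband.txt")),
               ds$validation_lists$proband)
})
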