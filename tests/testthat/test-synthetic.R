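test_that("generators are fully deterministic under a fixed seed", {
  spec <- synthetic_spec(n_genes = 60, n_planted = 3, seed = 7)
  expect_identical(generate_screen(spec), generate_screen(spec))
  expect_identical(generate_kg(spec), generate_kg(spec))
  expect_identical(generate_corpus(spec), generate_corpus(spec))
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  expect_identical(generate_rnaseq(spec), generate_rnaseq(spec))
  # substreams are independent: regenerating one input does not disturb another
  kg_before <- generate_kg(spec)
  invisible(generate_corpus(spec))
  expect_identical(generate_kg(spec), kg_before)
  # and a different seed changes the data
  spec2 <- synthetic_spec(n_genes = 60, n_planted = 3, seed = 8)
  expect_false(identical(generate_screen(spec2), generate_screen(spec)))
  expect_error(synthetic_spec(n_genes = 10, n_planted = 10, seed = 1))
  expect_error(synthetic_spec(seed = ), "seed")
})

test_that("planted screen genes pass the hit rules in every condition", {
  for (s in c(11, 12)) {
    spec <- synthetic_spec(n_genes = 120, n_planted = 4, seed = s)
    screens <- generate_screen(spec)
    planted <- attr(screens, "planted")
    for (cond in screens) {
      desi <- overall_desirability(cond$cvt, cond$cvp)
      pos_fdr <- cond$cvt$fdr[match(desi$gene, cond$cvt$gene)]
      hits <- call_hit(desi$overall, pos_fdr)
      expect_true(all(hits[desi$gene %in% planted]))
    }
  }
})

test_that("null genes almost never reach hit status", {
  rates <- vapply(1:3, function(s) {
    spec <- synthetic_spec(n_genes = 1000, n_planted = 1, seed = s,
                           conditions = default_conditions()[1:2, ])
    screens <- generate_screen(spec)
    planted <- attr(screens, "planted")
    hm <- hit_matrix(screens)
    mean(hm[setdiff(rownames(hm), planted), ])
  }, numeric(1))
  expect_lt(mean(rates), 0.005)
})

test_that("the synthetic graph carries typed anchors and binomial background", {
  spec <- synthetic_spec(n_genes = 100, n_planted = 5, seed = 13)
  kg <- generate_kg(spec)
  expect_true(all(c("EGFR", "NSCLC") %in% kg$nodes$id))
  expect_equal(kg$nodes$type[kg$nodes$id == "EGFR"], "gene")
  expect_equal(kg$nodes$type[kg$nodes$id == "NSCLC"], "disease")
  expect_true("interacts" %in% kg$edges$relation)
  expect_true(all(attr(kg, "cluster") %in% kg$nodes$id))

  # with no planted cluster the per-relation edge count is pure Erdos-Renyi
  spec0 <- synthetic_spec(n_genes = 200, n_planted = 5, seed = 17,
                          kg = list(n_relations = 2, background_p = 0.02,
                                    cluster_p = 0))
  kg0 <- generate_kg(spec0)
  n_nodes <- nrow(kg0$nodes)
  n_pairs <- choose(n_nodes, 2)
  for (rel in unique(kg0$edges$relation)) {
    got <- sum(kg0$edges$relation == rel)
    expected <- n_pairs * 0.02
    sigma <- sqrt(n_pairs * 0.02 * 0.98)
    expect_lt(abs(got - expected), 3 * sigma)
  }
})

test_that("corpus ground truth matches independent counting", {
  spec <- synthetic_spec(n_genes = 80, n_planted = 4, seed = 19,
                         corpus_size = 250)
  corpus <- generate_corpus(spec)
  truth <- attr(corpus, "truth")
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene[i]
    manual_egfr <- sum(vapply(corpus$docs, function(d) {
      all(c(g, "EGFR") %in% d$mentions)
    }, logical(1)))
    expect_equal(truth$comentions_EGFR[i], manual_egfr)
    expect_equal(comention_count(corpus, g, "EGFR"), manual_egfr)
  }
  # null genes co-mention EGFR at the configured base rate (binomial 3-sigma
  # band around p_mention * p_anchor, averaged over many null genes)
  gu <- synthetic_genes(spec)
  nulls <- setdiff(gu$genes, gu$planted)
  counts <- vapply(nulls, function(g) comention_count(corpus, g, "EGFR"),
                   numeric(1))
  p_co <- 0.02 * 0.6
  n_trials <- length(nulls) * length(corpus$docs)
  expect_lt(abs(sum(counts) - n_trials * p_co),
            3 * sqrt(n_trials * p_co * (1 - p_co)))
})

test_that("cohort labels are consistent with the responder rule by construction", {
  spec <- synthetic_spec(n_genes = 50, n_planted = 3, seed = 23)
  cohort <- generate_cohort(spec)
  truth <- attr(cohort, "truth")
  derived <- classify_responder(cohort$recist, cohort$pfs_months)
  expect_equal(derived, truth$intended)

  # planted genes enrich in non-responders on average across seeds
  planted_scores <- unlist(lapply(1:5, function(s) {
    sp <- synthetic_spec(n_genes = 50, n_planted = 3, seed = s)
    co <- generate_cohort(sp)
    gu <- synthetic_genes(sp)
    f <- clinical_features(co, gu$planted)
    unlist(f[, -1])
  }))
  expect_gt(mean(planted_scores), 0.5)

  # with no prevalence gap the planted scores centre at zero
  null_scores <- unlist(lapply(1:5, function(s) {
    sp <- synthetic_spec(n_genes = 50, n_planted = 3, seed = s,
                         cohort = list(trials = c("t1", "t2", "t3"),
                                       n_responders = 50,
                                       n_nonresponders = 50,
                                       base_prevalence = 0.05,
                                       responder_planted_prevalence = 0.1,
                                       planted_prevalence_gap = 0))
    co <- generate_cohort(sp)
    gu <- synthetic_genes(sp)
    unlist(clinical_features(co, gu$planted)[, -1])
  }))
  expect_lt(abs(mean(null_scores)), 0.35)
})

test_that("the assembled table carries the full hybrid feature set", {
  spec <- synthetic_spec(n_genes = 100, n_planted = 4, seed = 29)
  gu <- synthetic_genes(spec)
  ann <- generate_annotations(spec)
  ft <- assemble_feature_table(
    screens = generate_screen(spec), kg = generate_kg(spec),
    corpus = generate_corpus(spec), cohort = generate_cohort(spec),
    rnaseq = generate_rnaseq(spec), tractability = ann$tractability,
    essentiality = ann$essentiality)
  consistency <- c("ko_n_conditions_hit", "ko_n_cell_lines_hit",
                   "ko_n_treatments_hit", "act_n_conditions_hit",
                   "act_n_cell_lines_hit", "act_n_treatments_hit",
                   "full_screen")
  graph_feats <- c("degree", "unique_neighbors", "pagerank", "betweenness",
                   "dist_EGFR", "dist_NSCLC")
  lit_feats <- c("lit_EGFR", "lit_EGFR_norm", "lit_NSCLC", "lit_NSCLC_norm")
  expect_true(all(c(consistency, graph_feats, lit_feats,
                    "clinical_ES1", "clinical_ES2", "clinical_ES3",
                    "RNASeq_LFC", "RNASeq_pval",
                    "trac_ab", "trac_sm", "trac_other",
                    "nonessential") %in% feature_names(ft)))
  expect_length(feature_names(ft), 26)
  meta <- attr(ft, "feature_meta")
  expect_equal(sum(meta$category == "crispr"), 7)
  expect_equal(sum(meta$category == "graph"), 6)
  # planted genes are complete on every default objective
  obj <- default_preference()$objectives$feature
  planted_rows <- as.data.frame(ft)[match(gu$planted, ft$gene), obj]
  expect_false(anyNA(planted_rows))

  # module selection restricts the columns
  ft_cr <- assemble_feature_table(screens = generate_screen(spec),
                                  modules = "crispr")
  expect_equal(feature_names(ft_cr), consistency)
  expect_error(assemble_feature_table(screens = generate_screen(spec),
                                      modules = "graph"),
               "no knowledge graph")
})

test_that("fixture simulation is reproducible file by file", {
  spec <- synthetic_spec(n_genes = 40, n_planted = 3, seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_fixtures(spec, d1, force = TRUE)
  simulate_fixtures(spec, d2, force = TRUE)
  files <- list.files(d1, recursive = TRUE)
  expect_true(all(c("kg.tsv", "corpus.jsonl", "cohort.tsv", "rnaseq.tsv",
                    "tractability.tsv", "essentiality.tsv", "truth.json",
                    "manifest.json", "default_preference.yaml") %in% files))
  for (f in setdiff(files, "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  truth <- jsonlite::fromJSON(file.path(d1, "truth.json"))
  expect_length(truth$planted_genes, 3)
  # refusing to clobber a non-empty directory without force
  expect_error(simulate_fixtures(spec, d1), "not empty")
})
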