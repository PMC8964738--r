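test_that("corpora round-trip through JSON lines with unique document ids", {
  corpus <- toy_corpus()
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, p)
  back <- read_corpus(p)
  expect_equal(length(back$docs), 3)
  expect_equal(back$docs[[3]]$mentions, c("A", "EGFR", "NSCLC"))
  expect_error(lit_corpus(list(list(doc_id = "d", year = 2000, mentions = "x"),
                               list(doc_id = "d", year = 2001, mentions = "y"))),
               "unique")
  # year filter is inclusive on both ends
  filtered <- filter_corpus_years(corpus, from = 2005, to = 2010)
  expect_equal(length(filtered$docs), 2)
})

test_that("co-mention counting and normalisation follow set semantics", {
  corpus <- toy_corpus()
  expect_equal(comention_count(corpus, "A", "EGFR"), 2)
  expect_equal(comention_count(corpus, "A", "NSCLC"), 1)
  expect_equal(comention_count(corpus, "ZZZ", "EGFR"), 0)
  expect_equal(comention_count(corpus, "EGFR", "A"), 2)  # symmetric

  expect_equal(normalized_comention(corpus, "A", "EGFR"), 2 / 3)
  expect_equal(normalized_comention(corpus, "ZZZ", "EGFR"), 0)
  # a gene mentioned only alongside the term scores the upper bound 1
  only <- lit_corpus(list(list(doc_id = "d", year = 2001,
                               mentions = c("B", "EGFR"))))
  expect_equal(normalized_comention(only, "B", "EGFR"), 1)

  set.seed(61)
  for (i in 1:10) {
    rc <- random_corpus(20, c(LETTERS[1:6], "EGFR"))
    g <- sample(LETTERS[1:6], 1)
    expect_gte(normalized_comention(rc, g, "EGFR"), 0)
    expect_lte(normalized_comention(rc, g, "EGFR"), 1)
  }
})

test_that("the co-occurrence matrix equals brute-force pairwise intersection", {
  set.seed(67)
  genes <- LETTERS[1:8]
  for (i in 1:8) {
    rc <- random_corpus(sample(5:50, 1), c(genes, "EGFR"), p = runif(1, 0.1, 0.6))
    M <- cooccurrence_matrix(rc, genes)
    expect_true(isSymmetric(M))
    # brute force: count document-set intersections entity by entity
    docs_of <- lapply(genes, function(g) {
      which(vapply(rc$docs, function(d) g %in% d$mentions, logical(1)))
    })
    for (a in seq_along(genes)) {
      for (b in seq_along(genes)) {
        expect_equal(M[a, b], length(intersect(docs_of[[a]], docs_of[[b]])))
      }
    }
    expect_true(all(M <= pmin(outer(diag(M), diag(M), pmin))))
  }
})

test_that("responder classification requires CR/PR and PFS beyond 6 months", {
  expect_equal(classify_responder("CR", 8), "responder")
  expect_equal(classify_responder("PR", 5), "non_responder")
  expect_equal(classify_responder("PD", 12), "non_responder")
  expect_equal(classify_responder("PR", 6), "non_responder")  # strict >
  expect_equal(classify_responder(c("CR", "SD"), c(7, 7)),
               c("responder", "non_responder"))
  expect_error(classify_responder("NE", 3), "unknown RECIST")
})

toy_cohort <- function(n_alt_resp, n_alt_nonresp, n_resp = 10, n_nonresp = 10,
                       gene = "MET", trial = "trial_A") {
  alts <- c(lapply(seq_len(n_resp), function(i) {
    if (i <= n_alt_resp) gene else character(0)
  }), lapply(seq_len(n_nonresp), function(i) {
    if (i <= n_alt_nonresp) gene else character(0)
  }))
  df <- data.frame(
    patient_id = sprintf("p%02d", seq_len(n_resp + n_nonresp)),
    trial = trial,
    recist = c(rep("PR", n_resp), rep("PD", n_nonresp)),
    pfs_months = c(rep(12, n_resp), rep(2, n_nonresp)))
  df$alterations <- alts
  clinical_cohort(df)
}

test_that("clinical enrichment is a log2 prevalence ratio, trial-specific", {
  co <- toy_cohort(1, 4)
  # 4/10 vs 1/10 altered, no pseudocount: log2(0.4 / 0.1) = 2
  res <- clinical_enrichment(co, "MET", pseudocount = 0)
  expect_equal(res$enrichment, 2)
  expect_equal(res$altered_nonresponders, 4)
  expect_equal(res$altered_responders, 1)

  expect_equal(clinical_enrichment(toy_cohort(3, 3), "MET")$enrichment, 0)
  # never altered: log2(eps/eps) = 0 under the pseudocount convention
  expect_equal(clinical_enrichment(toy_cohort(0, 0), "MET")$enrichment, 0)
  # antisymmetry: swapping group prevalences negates the score (eps = 0)
  fwd <- clinical_enrichment(toy_cohort(2, 6), "MET", pseudocount = 0)
  rev <- clinical_enrichment(toy_cohort(6, 2), "MET", pseudocount = 0)
  expect_equal(fwd$enrichment, -rev$enrichment)

  # a trial without responders reports a missing score
  df <- data.frame(patient_id = c("a", "b"), trial = "t",
                   recist = c("PD", "PD"), pfs_months = c(1, 2))
  df$alterations <- list("MET", character(0))
  res_na <- clinical_enrichment(clinical_cohort(df), "MET")
  expect_true(is.na(res_na$enrichment))
})

test_that("per-trial feature columns agree with the single-gene path", {
  spec <- synthetic_spec(n_genes = 40, n_planted = 4, seed = 71)
  cohort <- generate_cohort(spec)
  gu <- synthetic_genes(spec)
  feats <- clinical_features(cohort, gu$genes)
  expect_equal(names(feats), c("gene", "clinical_ES1", "clinical_ES2",
                               "clinical_ES3"))
  trials <- attr(feats, "trials")
  for (g in sample(gu$genes, 5)) {
    single <- clinical_enrichment(cohort, g)
    expect_equal(unlist(feats[feats$gene == g, -1], use.names = FALSE),
                 single$enrichment[match(trials, single$trial)])
  }
})

test_that("cohort TSV round-trip preserves alteration sets", {
  spec <- synthetic_spec(n_genes = 30, n_planted = 3, seed = 73)
  cohort <- generate_cohort(spec)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, p)
  back <- read_cohort(p)
  expect_equal(back$patient_id, cohort$patient_id)
  expect_equal(back$alterations, cohort$alterations)
  expect_equal(back$pfs_months, cohort$pfs_months, tolerance = 1e-6)
})

test_that("tractability reversal is the documented involution", {
  expect_equal(reverse_tractability(1), 10L)
  expect_equal(reverse_tractability(10), 1L)
  expect_equal(reverse_tractability(reverse_tractability(1:10)), 1:10)
  expect_equal(sort(reverse_tractability(1:10)), 1:10)  # bijection
  expect_equal(reverse_tractability(2, max_bucket = 5), 4L)
  expect_error(reverse_tractability(0), "\\[1, 10\\]")
  expect_error(reverse_tractability(11), "\\[1, 10\\]")
  expect_error(reverse_tractability(2.5), "integers")
})

test_that("essentiality flag switches at 90% dependency, boundary inclusive", {
  expect_equal(essentiality_flag(0.95), "essential")
  expect_equal(essentiality_flag(0.5), "nonessential")
  expect_equal(essentiality_flag(0.9), "essential")
  expect_equal(essentiality_flag(c(0.899, 0.9, 0.901)),
               c("nonessential", "essential", "essential"))
  expect_error(essentiality_flag(1.5), "\\[0, 1\\]")
})
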