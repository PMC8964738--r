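#' Specification for the synthetic study
#'
#' Describes one synthetic re-ranking study with planted ground truth: a
#' gene universe in which a handful of planted resistance drivers carry
#' strong, concordant signal in every input (screen, knowledge graph,
#' literature, clinic, transcriptome) against a null background. Defaults
#' emulate the scale of a two-cell-line, two-treatment, dual-technology
#' resistance screen feeding a desk-scale evidence stack.
#'
#' @param n_genes gene universe size (default 500).
#' @param n_planted number of planted resistance genes (default 5); must be
#'   smaller than `n_genes`.
#' @param conditions data.frame of screen conditions with columns
#'   `cell_line`, `treatment`, `technology`; defaults to the full
#'   PC-9/HCC827 x gefitinib/osimertinib x KO/activation grid.
#' @param planted_effect_sd_multiple how many null-LFC standard deviations
#'   above the null mean planted genes sit (default 4, safely beyond the
#'   3-SD hit boundary).
#' @param null_essential_rate fraction of null genes flagged essential per
#'   comparison (default 0.05).
#' @param corpus_size number of synthetic documents (default 300).
#' @param kg list: `n_relations` (>= 1; the first relation is always
#'   `interacts`), `background_p` (Erdos-Renyi edge probability, default
#'   0.01), `cluster_p` (within-planted-cluster edge probability, default
#'   0.9).
#' @param cohort list: `trials` (names), `n_responders`,
#'   `n_nonresponders` per trial, `base_prevalence` (alteration rate of
#'   null genes and of planted genes in responders, default 0.05 / 0.1) and
#'   `planted_prevalence_gap` added for planted genes in non-responders
#'   (default 0.3).
#' @param seed integer seed; required. Each generator draws from its own
#'   substream derived from this seed, so individual inputs can be
#'   regenerated in isolation.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 500L, n_planted = 5L,
                           conditions = default_conditions(),
                           planted_effect_sd_multiple = 4,
                           null_essential_rate = 0.05,
                           corpus_size = 300L,
                           kg = list(n_relations = 3L, background_p = 0.01,
                                     cluster_p = 0.9),
                           cohort = list(trials = c("trial_A", "trial_B",
                                                    "trial_C"),
                                         n_responders = 50L,
                                         n_nonresponders = 50L,
                                         base_prevalence = 0.05,
                                         responder_planted_prevalence = 0.1,
                                         planted_prevalence_gap = 0.3),
                           seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_genes >= 2L, n_planted >= 1L, n_planted < n_genes,
            corpus_size >= 1L, is.data.frame(conditions),
            all(c("cell_line", "treatment", "technology") %in%
                  names(conditions)))
  structure(list(n_genes = as.integer(n_genes),
                 n_planted = as.integer(n_planted),
                 conditions = conditions,
                 planted_effect_sd_multiple = planted_effect_sd_multiple,
                 null_essential_rate = null_essential_rate,
                 corpus_size = as.integer(corpus_size),
                 kg = kg, cohort = cohort,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default screen condition grid
#' @return data.frame crossing two EGFR-mutant cell lines, two EGFR
#'   inhibitors and the two screen technologies (8 conditions).
#' @export
default_conditions <- function() {
  expand.grid(cell_line = c("PC-9", "HCC827"),
              treatment = c("gefitinib", "osimertinib"),
              technology = c("KO", "activation"),
              stringsAsFactors = FALSE)
}

# Independent substreams: generator k always sees the k-th derived seed.
substream_seed <- function(spec, k) {
  set.seed(spec$seed)
  sample.int(2147483646L, 10L)[k]
}

#' Gene universe and planted genes of a spec
#' @param spec a [synthetic_spec()]
#' @return list with `genes` (all ids) and `planted` (the planted subset,
#'   deterministic for the spec's seed).
#' @export
synthetic_genes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  set.seed(substream_seed(spec, 1L))
  planted <- sort(sample(genes, spec$n_planted))
  list(genes = genes, planted = planted)
}

#' Generate synthetic screen comparison tables
#'
#' For every condition of the spec, a CvT and a CvP table. Null genes draw
#' LFC ~ Normal(0, 1) and p ~ Uniform(0, 1); FDR columns are
#' Benjamini-Hochberg adjustments of the p-values. Planted genes sit
#' `planted_effect_sd_multiple` null standard deviations above the null LFC
#' mean with p <= 1e-5 and are never flagged essential, so they pass the
#' desirability hit rules in every condition by construction.
#'
#' @param spec a [synthetic_spec()]
#' @return list with one element per condition, each a list
#'   `(cvt, cvp)` of [screen_comparison()] tables, plus attribute `planted`.
#' @export
generate_screen <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gu <- synthetic_genes(spec)
  genes <- gu$genes
  is_planted <- genes %in% gu$planted
  set.seed(substream_seed(spec, 2L))
  out <- list()
  for (ci in seq_len(nrow(spec$conditions))) {
    cond <- spec$conditions[ci, ]
    make_cvt <- function() {
      lfc <- rnorm(length(genes))
      m <- mean(lfc[!is_planted]); s <- stats::sd(lfc[!is_planted])
      lfc[is_planted] <- m + spec$planted_effect_sd_multiple * s +
        runif(sum(is_planted), 0, 0.25 * s)
      p <- runif(length(genes))
      p[is_planted] <- 10^runif(sum(is_planted), -7, -5)
      fdr <- p.adjust(p, method = "BH")
      ess <- runif(length(genes)) < spec$null_essential_rate
      ess[is_planted] <- FALSE
      screen_comparison(genes, lfc, p, fdr, ess, comparison = "CvT",
                        cell_line = cond$cell_line,
                        treatment = cond$treatment,
                        technology = cond$technology)
    }
    make_cvp <- function() {
      lfc <- rnorm(length(genes))
      p <- runif(length(genes))
      ess <- runif(length(genes)) < spec$null_essential_rate
      ess[is_planted] <- FALSE
      screen_comparison(genes, lfc, p, p.adjust(p, "BH"), ess,
                        comparison = "CvP",
                        cell_line = cond$cell_line,
                        treatment = cond$treatment,
                        technology = cond$technology)
    }
    out[[condition_label(as.list(cond))]] <- list(cvt = make_cvt(),
                                                  cvp = make_cvp())
  }
  structure(out, planted = gu$planted)
}

#' Generate a synthetic knowledge graph
#'
#' Erdos-Renyi background across all relation types plus a dense planted
#' cluster containing the anchors `EGFR` and `NSCLC` and the planted genes,
#' so that planted genes are structurally close to the anchors. The first
#' relation is always `interacts` (the PPI view); two compound nodes are
#' included for type heterogeneity.
#'
#' @param spec a [synthetic_spec()]
#' @return A [knowledge_graph()] with attribute `cluster` (the planted
#'   cluster's node ids).
#' @export
generate_kg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gu <- synthetic_genes(spec)
  anchors <- c("EGFR", "NSCLC")
  compounds <- c("gefitinib", "osimertinib")
  ids <- c(gu$genes, anchors, compounds)
  types <- c(rep("gene", length(gu$genes)), "gene", "disease",
             rep("compound", 2L))
  rels <- c("interacts",
            paste0("rel_", seq_len(max(0L, spec$kg$n_relations - 1L))))
  set.seed(substream_seed(spec, 3L))
  edges <- list()
  n <- length(ids)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  for (rel in rels) {
    keep <- runif(nrow(pairs)) < spec$kg$background_p
    edges[[rel]] <- data.frame(source = ids[pairs[keep, 1L]],
                               relation = rep(rel, sum(keep)),
                               target = ids[pairs[keep, 2L]])
  }
  cluster <- c(gu$planted, anchors)
  cp <- utils::combn(cluster, 2L)
  for (rel in rels) {
    keep <- runif(ncol(cp)) < spec$kg$cluster_p
    edges[[paste0(rel, "_cluster")]] <- data.frame(source = cp[1L, keep],
                                                   relation = rep(rel, sum(keep)),
                                                   target = cp[2L, keep])
  }
  all_edges <- unique(do.call(rbind, c(edges, make.row.names = FALSE)))
  kg <- knowledge_graph(all_edges, data.frame(id = ids, type = types))
  attr(kg, "cluster") <- cluster
  kg
}

#' Generate a synthetic literature corpus
#'
#' Documents mention the anchors frequently, planted genes at an elevated
#' rate and null genes at a low base rate, so planted genes accumulate
#' co-mentions with `EGFR`/`NSCLC`. The exact realised co-mention counts of
#' the planted genes are recorded as ground truth.
#'
#' @param spec a [synthetic_spec()]
#' @param planted_mention_rate,null_mention_rate per-document mention
#'   probabilities (defaults 0.3 and 0.02).
#' @param anchor_rates named probabilities for the anchor terms.
#' @return A [lit_corpus()] with attribute `truth`: data.frame of planted
#'   genes and their realised co-mention counts with each anchor.
#' @export
generate_corpus <- function(spec, planted_mention_rate = 0.3,
                            null_mention_rate = 0.02,
                            anchor_rates = c(EGFR = 0.6, NSCLC = 0.5)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gu <- synthetic_genes(spec)
  set.seed(substream_seed(spec, 4L))
  rate <- ifelse(gu$genes %in% gu$planted,
                 planted_mention_rate, null_mention_rate)
  docs <- vector("list", spec$corpus_size)
  for (d in seq_len(spec$corpus_size)) {
    mentions <- gu$genes[runif(length(gu$genes)) < rate]
    for (a in names(anchor_rates)) {
      if (runif(1) < anchor_rates[[a]]) mentions <- c(mentions, a)
    }
    docs[[d]] <- list(doc_id = sprintf("doc%05d", d),
                      year = sample(2000:2019, 1L),
                      mentions = mentions)
  }
  corpus <- lit_corpus(docs)
  counts <- lapply(names(anchor_rates), function(a) {
    vapply(gu$planted, function(g) comention_count(corpus, g, a), numeric(1))
  })
  truth <- data.frame(gene = gu$planted)
  for (i in seq_along(anchor_rates)) {
    truth[[paste0("comentions_", names(anchor_rates)[i])]] <-
      as.integer(counts[[i]])
  }
  attr(corpus, "truth") <- truth
  corpus
}

#' Generate a synthetic clinical cohort
#'
#' Per trial, responders and non-responders whose RECIST class and PFS are
#' consistent with the responder rule by construction (responders: CR/PR and
#' PFS > 6; non-responders: either SD/PD, or CR/PR with PFS <= 6). Planted
#' genes are altered with a prevalence gap towards non-responders; null
#' genes at the base rate in both groups.
#'
#' @param spec a [synthetic_spec()]
#' @return A [clinical_cohort()] with attribute `truth` (intended responder
#'   label per patient).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gu <- synthetic_genes(spec)
  co <- spec$cohort
  set.seed(substream_seed(spec, 5L))
  rows <- list()
  for (tr in co$trials) {
    n_r <- co$n_responders; n_n <- co$n_nonresponders
    lab <- c(rep("responder", n_r), rep("non_responder", n_n))
    recist <- c(sample(c("CR", "PR"), n_r, replace = TRUE,
                       prob = c(0.2, 0.8)),
                ifelse(runif(n_n) < 0.7,
                       sample(c("SD", "PD"), n_n, replace = TRUE),
                       sample(c("CR", "PR"), n_n, replace = TRUE)))
    pfs <- numeric(n_r + n_n)
    pfs[lab == "responder"] <- runif(n_r, 6.1, 30)
    nonresp <- which(lab == "non_responder")
    pfs[nonresp] <- ifelse(recist[nonresp] %in% c("CR", "PR"),
                           runif(length(nonresp), 0, 5.9),
                           runif(length(nonresp), 0, 20))
    prev_r <- ifelse(gu$genes %in% gu$planted,
                     co$responder_planted_prevalence, co$base_prevalence)
    prev_n <- ifelse(gu$genes %in% gu$planted,
                     co$responder_planted_prevalence +
                       co$planted_prevalence_gap,
                     co$base_prevalence)
    alts <- lapply(seq_len(n_r + n_n), function(i) {
      prev <- if (lab[i] == "responder") prev_r else prev_n
      gu$genes[runif(length(gu$genes)) < prev]
    })
    rows[[tr]] <- data.frame(patient_id = sprintf("%s_p%03d", tr,
                                                  seq_len(n_r + n_n)),
                             trial = tr, recist = recist, pfs_months = pfs)
    rows[[tr]]$alterations <- alts
    rows[[tr]]$intended <- lab
  }
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  truth <- df[, c("patient_id", "trial", "intended")]
  df$intended <- NULL
  cohort <- clinical_cohort(df)
  attr(cohort, "truth") <- truth
  cohort
}

#' Generate a synthetic transcriptomic response table
#'
#' Emulates an acute-treatment RNA-seq contrast consumed as a plain per-gene
#' LFC / p-value table: planted genes are strongly upregulated with small
#' p-values, null genes draw from the null.
#'
#' @param spec a [synthetic_spec()]
#' @return data.frame with columns `gene`, `lfc`, `pvalue`.
#' @export
generate_rnaseq <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gu <- synthetic_genes(spec)
  set.seed(substream_seed(spec, 6L))
  is_planted <- gu$genes %in% gu$planted
  lfc <- rnorm(length(gu$genes))
  lfc[is_planted] <- rnorm(sum(is_planted), mean = 3, sd = 0.5)
  p <- runif(length(gu$genes))
  p[is_planted] <- 10^runif(sum(is_planted), -8, -4)
  data.frame(gene = gu$genes, lfc = lfc, pvalue = p)
}

#' Generate synthetic tractability buckets and essentiality fractions
#'
#' Buckets for three modalities (antibody, small molecule, other) drawn
#' uniformly; planted genes receive favourable small-molecule buckets.
#' Dependency fractions are low for most genes, with a small common-essential
#' tail; planted genes are never common-essential.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `tractability` (gene, bucket_ab, bucket_sm,
#'   bucket_other) and `essentiality` (gene, dependent_fraction).
#' @export
generate_annotations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gu <- synthetic_genes(spec)
  set.seed(substream_seed(spec, 7L))
  n <- length(gu$genes)
  is_planted <- gu$genes %in% gu$planted
  tract <- data.frame(gene = gu$genes,
                      bucket_ab = sample.int(10L, n, replace = TRUE),
                      bucket_sm = sample.int(10L, n, replace = TRUE),
                      bucket_other = sample.int(10L, n, replace = TRUE))
  tract$bucket_sm[is_planted] <- sample.int(3L, sum(is_planted),
                                            replace = TRUE)
  frac <- runif(n, 0, 0.6)
  common <- runif(n) < 0.05
  frac[common] <- runif(sum(common), 0.9, 1)
  frac[is_planted] <- runif(sum(is_planted), 0, 0.3)
  list(tractability = tract,
       essentiality = data.frame(gene = gu$genes, dependent_fraction = frac))
}

#' Write the full synthetic fixture set to disk
#'
#' Materialises every input the pipeline consumes, in the formats the
#' readers expect, plus ground-truth sidecars and a manifest (seed, package
#' version, per-file MD5 checksums). Downstream checks read truth from the
#' sidecars rather than re-deriving it.
#'
#' @param spec a [synthetic_spec()]
#' @param out_dir output directory; must be empty unless `force = TRUE`.
#' @param force overwrite a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
simulate_fixtures <- function(spec, out_dir, force = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop(sprintf("output directory %s is not empty (use force = TRUE)",
                 out_dir))
  }
  dir.create(file.path(out_dir, "screens"), recursive = TRUE,
             showWarnings = FALSE)
  gu <- synthetic_genes(spec)
  screens <- generate_screen(spec)
  for (lab in names(screens)) {
    for (cmp in c("cvt", "cvp")) {
      tab <- screens[[lab]][[cmp]]
      cond <- attr(tab, "condition")
      out <- data.frame(tab,
                        cell_line = cond$cell_line,
                        treatment = cond$treatment,
                        technology = cond$technology,
                        comparison = attr(tab, "comparison"))
      fn <- file.path(out_dir, "screens",
                      sprintf("%s_%s.tsv", gsub("[^A-Za-z0-9]+", "_", lab),
                              toupper(cmp)))
      write.table(out, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  kg <- generate_kg(spec)
  write_kg(kg, file.path(out_dir, "kg.tsv"),
           node_path = file.path(out_dir, "kg_nodes.tsv"))
  corpus <- generate_corpus(spec)
  write_corpus(corpus, file.path(out_dir, "corpus.jsonl"))
  cohort <- generate_cohort(spec)
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
  rnaseq <- generate_rnaseq(spec)
  write.table(rnaseq, file.path(out_dir, "rnaseq.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ann <- generate_annotations(spec)
  write.table(ann$tractability, file.path(out_dir, "tractability.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ann$essentiality, file.path(out_dir, "essentiality.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_preference(default_preference(),
                   file.path(out_dir, "default_preference.yaml"))
  truth <- list(planted_genes = gu$planted,
                kg_cluster = attr(kg, "cluster"),
                corpus_comentions = attr(corpus, "truth"),
                cohort_labels = attr(cohort, "truth"))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(seed = spec$seed,
                   n_genes = spec$n_genes,
                   n_planted = spec$n_planted,
                   package = "crisprank",
                   version = as.character(utils::packageVersion("crisprank")),
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
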