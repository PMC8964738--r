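#' Construct a literature corpus
#'
#' A corpus abstracted to the level this package needs: each document is a
#' set of entity mentions (gene symbols and key terms) extracted upstream by
#' whatever NLP pipeline produced the data, plus a publication year.
#'
#' @param docs list of documents, each a list with elements `doc_id`, `year`
#'   and `mentions` (character vector, possibly empty).
#' @return An object of class `lit_corpus`.
#' @export
lit_corpus <- function(docs) {
  stopifnot(is.list(docs))
  ids <- vapply(docs, function(d) as.character(d$doc_id), character(1))
  if (anyDuplicated(ids)) stop("document ids must be unique")
  docs <- lapply(docs, function(d) {
    if (is.null(d$mentions)) stop("document without a mention set")
    list(doc_id = as.character(d$doc_id),
         year = as.integer(d$year),
         mentions = unique(as.character(d$mentions)))
  })
  structure(list(docs = docs), class = "lit_corpus")
}

#' @export
print.lit_corpus <- function(x, ...) {
  cat(sprintf("<lit_corpus> %d documents\n", length(x$docs)))
  invisible(x)
}

#' Read a corpus from JSON lines
#' @param path file with one JSON object per line:
#'   `{"doc_id": ..., "year": ..., "mentions": [...]}`.
#' @return A [lit_corpus()].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lit_corpus(lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE))
}

#' Write a corpus to JSON lines
#' @param corpus a [lit_corpus()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "lit_corpus"))
  lines <- vapply(corpus$docs, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, year = d$year,
                          mentions = d$mentions),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a corpus to a publication-year window
#' @param corpus a [lit_corpus()]
#' @param from,to inclusive year bounds.
#' @return A filtered [lit_corpus()].
#' @export
filter_corpus_years <- function(corpus, from = 2000L, to = 2019L) {
  stopifnot(inherits(corpus, "lit_corpus"))
  keep <- vapply(corpus$docs, function(d) {
    !is.na(d$year) && d$year >= from && d$year <= to
  }, logical(1))
  structure(list(docs = corpus$docs[keep]), class = "lit_corpus")
}

#' Count documents co-mentioning a gene and a key term
#'
#' The proxy of literature support: the number of documents whose mention
#' set contains both entities. Entities absent from the corpus simply count
#' zero. Symmetric in its two entity arguments.
#'
#' @param corpus a [lit_corpus()]
#' @param gene,term entity strings.
#' @return non-negative integer count.
#' @export
comention_count <- function(corpus, gene, term) {
  stopifnot(inherits(corpus, "lit_corpus"))
  sum(vapply(corpus$docs, function(d) {
    gene %in% d$mentions && term %in% d$mentions
  }, logical(1)))
}

#' Normalised co-mention frequency
#'
#' Co-mention count divided by the number of documents mentioning the gene
#' at all, so that heavily-published genes are not favoured merely by volume.
#' A gene never mentioned scores 0 by convention.
#'
#' @inheritParams comention_count
#' @return real in \[0, 1\].
#' @export
normalized_comention <- function(corpus, gene, term) {
  stopifnot(inherits(corpus, "lit_corpus"))
  n_gene <- sum(vapply(corpus$docs, function(d) gene %in% d$mentions,
                       logical(1)))
  if (n_gene == 0L) return(0)
  comention_count(corpus, gene, term) / n_gene
}

# docs x entities 0/1 incidence over an entity list
mention_incidence <- function(corpus, entities) {
  m <- vapply(corpus$docs, function(d) entities %in% d$mentions,
              logical(length(entities)))
  m <- matrix(m, nrow = length(entities))
  rownames(m) <- entities
  t(m) * 1L
}

#' Gene co-occurrence matrix
#'
#' `M[i, j]` counts the documents mentioning both gene i and gene j; the
#' diagonal holds per-gene document counts. Symmetric by construction and
#' bounded by `M[i, j] <= min(M[i, i], M[j, j])`.
#'
#' @param corpus a [lit_corpus()]
#' @param genes non-empty character vector of gene entities.
#' @return symmetric integer matrix with `genes` as dimnames.
#' @export
cooccurrence_matrix <- function(corpus, genes) {
  stopifnot(inherits(corpus, "lit_corpus"))
  if (!length(genes)) stop("genes must be non-empty")
  inc <- mention_incidence(corpus, genes)
  M <- crossprod(inc)
  storage.mode(M) <- "integer"
  M
}

#' Literature features for a gene list
#'
#' Computes, for every gene, the co-mention count with each key term and its
#' normalised frequency -- the four summary literature metrics for the
#' default terms `EGFR` and `NSCLC`.
#'
#' @param corpus a [lit_corpus()]
#' @param genes character vector of gene entities.
#' @param terms key terms of interest (default `c("EGFR", "NSCLC")`).
#' @return data.frame with columns `gene`, `lit_<term>` and
#'   `lit_<term>_norm` for every term.
#' @export
literature_features <- function(corpus, genes, terms = c("EGFR", "NSCLC")) {
  stopifnot(inherits(corpus, "lit_corpus"), length(genes) >= 1L)
  inc_g <- mention_incidence(corpus, genes)        # docs x genes
  inc_t <- mention_incidence(corpus, terms)        # docs x terms
  counts <- crossprod(inc_g, inc_t)                # genes x terms
  n_gene <- colSums(inc_g)
  out <- data.frame(gene = genes, row.names = NULL)
  for (tm in terms) {
    out[[paste0("lit_", tm)]] <- as.numeric(counts[, tm])
    out[[paste0("lit_", tm, "_norm")]] <-
      ifelse(n_gene > 0, counts[, tm] / n_gene, 0)
  }
  out
}

#' Construct a clinical cohort
#'
#' Per-patient trial data: best RECIST response, progression-free survival
#' and the set of genes found altered in the patient's panel sequencing.
#'
#' @param patients data.frame with columns `patient_id`, `trial`, `recist`
#'   (CR/PR/SD/PD), `pfs_months` (>= 0) and `alterations` (either a
#'   list-column of character vectors or a semicolon-separated string
#'   column).
#' @return data.frame of class `clinical_cohort` with a list-column
#'   `alterations`.
#' @export
clinical_cohort <- function(patients) {
  stopifnot(is.data.frame(patients))
  need <- c("patient_id", "trial", "recist", "pfs_months", "alterations")
  if (!all(need %in% names(patients))) {
    stop("cohort needs columns patient_id, trial, recist, pfs_months, alterations")
  }
  patients$patient_id <- as.character(patients$patient_id)
  patients$trial <- as.character(patients$trial)
  patients$recist <- as.character(patients$recist)
  bad <- setdiff(unique(patients$recist), c("CR", "PR", "SD", "PD"))
  if (length(bad)) {
    stop(sprintf("unknown RECIST class: %s", paste(bad, collapse = ", ")))
  }
  if (any(patients$pfs_months < 0)) stop("pfs_months must be >= 0")
  key <- paste(patients$trial, patients$patient_id)
  if (anyDuplicated(key)) stop("patient ids must be unique within a trial")
  if (!is.list(patients$alterations)) {
    patients$alterations <- lapply(strsplit(as.character(patients$alterations),
                                            ";", fixed = TRUE),
                                   function(x) x[nzchar(x)])
  }
  class(patients) <- c("clinical_cohort", "data.frame")
  patients
}

#' Read a clinical cohort from TSV
#' @param path TSV with columns `patient_id`, `trial`, `recist`,
#'   `pfs_months`, `alterations` (semicolon-separated gene list).
#' @return A [clinical_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  df$pfs_months <- as.numeric(df$pfs_months)
  clinical_cohort(df)
}

#' Write a clinical cohort to TSV
#' @param cohort a [clinical_cohort()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  out <- as.data.frame(cohort)
  out$alterations <- vapply(cohort$alterations, paste, character(1),
                            collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify patients as responders
#'
#' A responder has a complete or partial RECIST response AND progression-free
#' survival strictly greater than 6 months; everything else (including CR/PR
#' with short PFS) is a non-responder.
#'
#' @param recist character vector of RECIST classes (CR/PR/SD/PD).
#' @param pfs_months non-negative progression-free survival in months.
#' @param pfs_cutoff months threshold (default 6).
#' @return character vector, `"responder"` or `"non_responder"`.
#' @export
#' @examples
#' classify_responder(c("CR", "PR", "PD"), c(8, 5, 12))
classify_responder <- function(recist, pfs_months, pfs_cutoff = 6) {
  bad <- setdiff(unique(recist), c("CR", "PR", "SD", "PD"))
  if (length(bad)) {
    stop(sprintf("unknown RECIST class: %s", paste(bad, collapse = ", ")))
  }
  ifelse(recist %in% c("CR", "PR") & pfs_months > pfs_cutoff,
         "responder", "non_responder")
}

#' Trial-specific clinical enrichment score of a gene
#'
#' For each trial separately (panels differ between trials, so scores are
#' never aggregated across them) the prevalence of alterations of the gene
#' is computed in responders and non-responders and summarised as
#' `log2((prev_nonresp + eps) / (prev_resp + eps))`: positive scores mean
#' the alteration is enriched in non-responders, i.e. associated with
#' resistance. The raw 2x2 counts are returned alongside so alternative
#' statistics can be derived. Trials missing either group report a missing
#' score.
#'
#' @param cohort a [clinical_cohort()]
#' @param gene gene identifier.
#' @param pseudocount additive prevalence pseudocount eps (default 0.01)
#'   keeping the score finite when a group has zero altered patients.
#' @return data.frame with one row per trial: `trial`, `n_responders`,
#'   `n_nonresponders`, `altered_responders`, `altered_nonresponders`,
#'   `enrichment`.
#' @export
clinical_enrichment <- function(cohort, gene, pseudocount = 0.01) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  status <- classify_responder(cohort$recist, cohort$pfs_months)
  altered <- vapply(cohort$alterations, function(a) gene %in% a, logical(1))
  trials <- sort(unique(cohort$trial))
  rows <- lapply(trials, function(tr) {
    sel <- cohort$trial == tr
    resp <- sel & status == "responder"
    nonr <- sel & status == "non_responder"
    n_r <- sum(resp); n_n <- sum(nonr)
    a_r <- sum(altered & resp); a_n <- sum(altered & nonr)
    score <- if (n_r == 0L || n_n == 0L) {
      NA_real_
    } else {
      log2((a_n / n_n + pseudocount) / (a_r / n_r + pseudocount))
    }
    data.frame(trial = tr, n_responders = n_r, n_nonresponders = n_n,
               altered_responders = a_r, altered_nonresponders = a_n,
               enrichment = score)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Clinical enrichment features for a gene list
#'
#' One feature column per trial (`clinical_ES1`, `clinical_ES2`, ... in
#' sorted trial order), each holding the trial-specific enrichment score of
#' [clinical_enrichment()].
#'
#' @inheritParams clinical_enrichment
#' @param genes character vector of genes.
#' @return data.frame with columns `gene` and one `clinical_ES<i>` per
#'   trial; attribute `trials` maps columns back to trial names.
#' @export
clinical_features <- function(cohort, genes, pseudocount = 0.01) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  status <- classify_responder(cohort$recist, cohort$pfs_months)
  trials <- sort(unique(cohort$trial))
  # patient x gene incidence via one unlist pass
  alt_gene <- unlist(cohort$alterations, use.names = FALSE)
  alt_patient <- rep(seq_len(nrow(cohort)),
                     lengths(cohort$alterations))
  keep <- alt_gene %in% genes
  inc <- matrix(FALSE, nrow(cohort), length(genes),
                dimnames = list(NULL, genes))
  inc[cbind(alt_patient[keep], match(alt_gene[keep], genes))] <- TRUE
  out <- data.frame(gene = genes, row.names = NULL)
  for (i in seq_along(trials)) {
    sel_r <- cohort$trial == trials[i] & status == "responder"
    sel_n <- cohort$trial == trials[i] & status == "non_responder"
    n_r <- sum(sel_r); n_n <- sum(sel_n)
    col <- if (n_r == 0L || n_n == 0L) {
      rep(NA_real_, length(genes))
    } else {
      prev_r <- colSums(inc[sel_r, , drop = FALSE]) / n_r
      prev_n <- colSums(inc[sel_n, , drop = FALSE]) / n_n
      log2((prev_n + pseudocount) / (prev_r + pseudocount))
    }
    out[[paste0("clinical_ES", i)]] <- as.numeric(col)
  }
  attr(out, "trials") <- trials
  out
}

#' Reverse a tractability bucket into a score
#'
#' Tractability pipelines assign ordinal buckets where bucket 1 is the most
#' druggable; reversing them yields a score where higher is better, with the
#' most druggable bucket mapping to the maximum score (10 under the default
#' 10-bucket scheme). The reversal is an involution.
#'
#' @param bucket integer vector of buckets in `[1, max_bucket]`.
#' @param max_bucket number of buckets (default 10).
#' @return integer vector of scores, `(max_bucket + 1) - bucket`.
#' @export
#' @examples
#' reverse_tractability(c(1, 10, 4))
reverse_tractability <- function(bucket, max_bucket = 10L) {
  if (any(!is.finite(bucket)) || any(bucket != round(bucket))) {
    stop("buckets must be integers")
  }
  if (any(bucket < 1 | bucket > max_bucket)) {
    stop(sprintf("buckets must lie in [1, %d]", max_bucket))
  }
  as.integer(max_bucket + 1L - bucket)
}

#' Flag common-essential genes
#'
#' A gene is flagged essential when inhibiting it reduces viability in at
#' least 90% of the DepMap-style cell-line panel (boundary inclusive);
#' essential genes make poor drug targets regardless of their resistance
#' evidence.
#'
#' @param dependent_fraction fraction of dependent cell lines in \[0, 1\].
#' @param threshold flagging threshold (default 0.9).
#' @return character vector, `"essential"` or `"nonessential"`.
#' @export
#' @examples
#' essentiality_flag(c(0.95, 0.5, 0.9))
essentiality_flag <- function(dependent_fraction, threshold = 0.9) {
  if (any(!is.finite(dependent_fraction)) ||
      any(dependent_fraction < 0 | dependent_fraction > 1)) {
    stop("dependent_fraction must lie in [0, 1]")
  }
  ifelse(dependent_fraction >= threshold, "essential", "nonessential")
}
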