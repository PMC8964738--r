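#' Graph-derived features for a gene list
#'
#' Follows the split used throughout this framework: descriptive structure
#' (degree, unique neighbours) and embeddings (RESCAL, anchor distances) are
#' computed on the full heterogeneous graph, while centrality (PageRank,
#' betweenness) is computed on the PPI view ([ppi_subgraph()]), where
#' centrality has a mechanistic reading. Genes absent from the PPI subgraph
#' have no interaction support and score 0 on both centralities.
#'
#' @param kg a [knowledge_graph()] containing every gene as a node.
#' @param genes character vector of gene node ids.
#' @param anchors anchor entity ids for embedding distances.
#' @param ppi_relation relation defining the PPI view (default
#'   `"interacts"`).
#' @param rank,iterations,regularization,seed passed to [rescal_fit()].
#' @param centrality_scope `"ppi"` (default) or `"full"` -- which graph the
#'   centralities are computed on.
#' @return data.frame with columns `gene`, `degree`, `unique_neighbors`,
#'   `pagerank`, `betweenness` and one `dist_<anchor>` per anchor.
#' @export
kg_feature_table <- function(kg, genes, anchors = c("EGFR", "NSCLC"),
                             ppi_relation = "interacts",
                             rank = 8L, iterations = 30L,
                             regularization = 0.01, seed = 1L,
                             centrality_scope = c("ppi", "full")) {
  stopifnot(inherits(kg, "knowledge_graph"))
  centrality_scope <- match.arg(centrality_scope)
  missing <- setdiff(genes, kg$nodes$id)
  if (length(missing)) {
    stop(sprintf("gene(s) absent from the graph: %s",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  sm <- structural_metrics(kg)
  sm <- sm[match(genes, sm$node), ]
  cg <- if (centrality_scope == "ppi") ppi_subgraph(kg, ppi_relation) else kg
  pr <- kg_pagerank(cg)
  bt <- kg_betweenness(cg)
  pagerank <- ifelse(genes %in% names(pr), pr[genes], 0)
  betweenness <- ifelse(genes %in% names(bt), bt[genes], 0)
  emb <- rescal_fit(kg, rank = rank, iterations = iterations,
                    regularization = regularization, seed = seed)
  D <- anchor_distances(emb, genes, anchors)
  out <- data.frame(gene = genes,
                    degree = sm$degree,
                    unique_neighbors = sm$unique_neighbors,
                    pagerank = as.numeric(pagerank),
                    betweenness = as.numeric(betweenness),
                    row.names = NULL)
  for (a in anchors) out[[paste0("dist_", a)]] <- D[, a]
  out
}

#' Assemble the hybrid feature table
#'
#' Runs every feature module and joins the columns into one
#' [feature_table()] over a shared gene universe: seven screen-consistency
#' features, six graph features, four literature metrics, one clinical
#' enrichment score per trial, the transcriptomic LFC/p-value pair, three
#' reversed tractability scores and the essentiality flag (encoded as
#' `nonessential` 0/1 so that, like every other feature, higher is more
#' attractive). Category metadata is attached per column.
#'
#' @param screens list of conditions (each `list(cvt, cvp)`), as produced by
#'   [generate_screen()] or read from disk.
#' @param kg a [knowledge_graph()]
#' @param corpus a [lit_corpus()]
#' @param cohort a [clinical_cohort()]
#' @param rnaseq data.frame with columns `gene`, `lfc`, `pvalue`.
#' @param tractability data.frame with columns `gene`, `bucket_ab`,
#'   `bucket_sm`, `bucket_other`.
#' @param essentiality data.frame with columns `gene`,
#'   `dependent_fraction`.
#' @param genes gene universe; defaults to the genes of the first screen
#'   comparison. All inputs must cover it.
#' @param anchors,rescal_rank,rescal_iterations,rescal_seed graph-feature
#'   controls, see [kg_feature_table()].
#' @param modules subset of
#'   `c("crispr", "graph", "literature", "clinical", "preclinical",
#'   "tractability", "essentiality")` to assemble (default all). Inputs of
#'   unselected modules may be NULL.
#' @return A [feature_table()] with feature metadata.
#' @export
assemble_feature_table <- function(screens = NULL, kg = NULL, corpus = NULL,
                                   cohort = NULL, rnaseq = NULL,
                                   tractability = NULL, essentiality = NULL,
                                   genes = NULL,
                                   anchors = c("EGFR", "NSCLC"),
                                   rescal_rank = 8L,
                                   rescal_iterations = 30L,
                                   rescal_seed = 1L,
                                   modules = feature_categories) {
  modules <- match.arg(modules, feature_categories, several.ok = TRUE)
  if (is.null(genes)) {
    if (is.null(screens)) stop("supply 'genes' or 'screens'")
    genes <- screens[[1L]]$cvt$gene
  }
  check_universe <- function(have, what) {
    miss <- setdiff(genes, have)
    if (length(miss)) {
      stop(sprintf("%s does not cover the gene universe (missing %s%s)",
                   what, paste(head(miss, 3L), collapse = ", "),
                   if (length(miss) > 3L) ", ..." else ""))
    }
  }
  out <- data.frame(gene = genes)
  meta <- list()
  add <- function(df, category, descriptions) {
    df <- df[match(genes, df$gene), , drop = FALSE]
    for (f in setdiff(names(df), "gene")) {
      out[[f]] <<- as.numeric(df[[f]])
      meta[[f]] <<- data.frame(feature = f, category = category,
                               description = descriptions[[f]] %||% f)
    }
  }
  if ("crispr" %in% modules) {
    if (is.null(screens)) stop("crispr module selected but no screens given")
    hm <- hit_matrix(screens)
    cf <- consistency_features(hm)
    check_universe(cf$gene, "screen data")
    add(cf, "crispr", list(
      full_screen = "distinct cell lines where the gene is a hit, any technology"))
  }
  if ("graph" %in% modules) {
    if (is.null(kg)) stop("graph module selected but no knowledge graph given")
    gf <- kg_feature_table(kg, genes, anchors = anchors,
                           rank = rescal_rank,
                           iterations = rescal_iterations,
                           seed = rescal_seed)
    add(gf, "graph", list(
      pagerank = "PageRank on the PPI subgraph",
      betweenness = "betweenness centrality on the PPI subgraph"))
  }
  if ("literature" %in% modules) {
    if (is.null(corpus)) stop("literature module selected but no corpus given")
    lf <- literature_features(corpus, genes, terms = anchors)
    add(lf, "literature", list())
  }
  if ("clinical" %in% modules) {
    if (is.null(cohort)) stop("clinical module selected but no cohort given")
    cl <- clinical_features(cohort, genes)
    add(cl, "clinical", list())
  }
  if ("preclinical" %in% modules) {
    if (is.null(rnaseq)) stop("preclinical module selected but no rnaseq table given")
    check_universe(rnaseq$gene, "rnaseq table")
    rn <- data.frame(gene = rnaseq$gene, RNASeq_LFC = rnaseq$lfc,
                     RNASeq_pval = rnaseq$pvalue)
    add(rn, "preclinical", list(
      RNASeq_LFC = "log2 fold-change, acute-treatment transcriptomic contrast",
      RNASeq_pval = "p-value of the transcriptomic contrast"))
  }
  if ("tractability" %in% modules) {
    if (is.null(tractability)) stop("tractability module selected but no table given")
    check_universe(tractability$gene, "tractability table")
    tr <- data.frame(gene = tractability$gene,
                     trac_ab = reverse_tractability(tractability$bucket_ab),
                     trac_sm = reverse_tractability(tractability$bucket_sm),
                     trac_other = reverse_tractability(tractability$bucket_other))
    add(tr, "tractability", list())
  }
  if ("essentiality" %in% modules) {
    if (is.null(essentiality)) stop("essentiality module selected but no table given")
    check_universe(essentiality$gene, "essentiality table")
    es <- data.frame(gene = essentiality$gene,
                     nonessential = as.numeric(
                       essentiality_flag(essentiality$dependent_fraction) ==
                         "nonessential"))
    add(es, "essentiality",
        list(nonessential = "1 unless >= 90% of cell lines depend on the gene"))
  }
  feature_table(out, meta = do.call(rbind, c(unname(meta),
                                             make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
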