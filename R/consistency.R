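#' Build a gene-by-condition hit matrix
#'
#' Runs [overall_desirability()] and [call_hit()] for every screen condition
#' and records the boolean outcome in one matrix: rows are genes, columns are
#' cell line x treatment x technology conditions.
#'
#' @param screens list of conditions, each a list with elements `cvt` and
#'   `cvp` ([screen_comparison()] tables for the same condition).
#' @param mode,shape passed to [overall_desirability()].
#' @param desi_cutoff,fdr_cutoff passed to [call_hit()].
#' @return A logical matrix of class `hit_matrix` with unique condition
#'   labels as column names and a `conditions` attribute (data.frame with
#'   columns `label`, `cell_line`, `treatment`, `technology`).
#' @export
hit_matrix <- function(screens, mode = "resistance", shape = 2,
                       desi_cutoff = 0.7, fdr_cutoff = 0.1) {
  stopifnot(is.list(screens), length(screens) >= 1L)
  genes <- NULL
  cols <- list()
  conds <- list()
  for (sc in screens) {
    stopifnot(!is.null(sc$cvt), !is.null(sc$cvp))
    desi <- overall_desirability(sc$cvt, sc$cvp, mode = mode, shape = shape)
    cond <- attr(desi, "condition")
    lab <- condition_label(cond)
    if (lab %in% names(cols)) {
      stop(sprintf("duplicated condition label '%s'", lab))
    }
    pos_fdr <- sc$cvt$fdr[match(desi$gene, sc$cvt$gene)]
    hit <- call_hit(desi$overall, pos_fdr,
                    desi_cutoff = desi_cutoff, fdr_cutoff = fdr_cutoff)
    names(hit) <- desi$gene
    if (is.null(genes)) genes <- desi$gene else genes <- union(genes, desi$gene)
    cols[[lab]] <- hit
    conds[[lab]] <- data.frame(label = lab, cell_line = cond$cell_line,
                               treatment = cond$treatment,
                               technology = cond$technology)
  }
  m <- matrix(FALSE, nrow = length(genes), ncol = length(cols),
              dimnames = list(genes, names(cols)))
  for (lab in names(cols)) {
    h <- cols[[lab]]
    m[names(h), lab] <- h
  }
  structure(m, conditions = do.call(rbind, c(conds, make.row.names = FALSE)),
            class = c("hit_matrix", class(m)))
}

#' Cross-condition consistency features
#'
#' Genes behaving consistently across related conditions are what a manual
#' triage would rank up; this encodes that intuition as exactly seven integer
#' features per gene: for each screen technology (KO and activation) the
#' number of conditions, of distinct cell lines and of distinct treatments in
#' which the gene was called a hit, plus `full_screen`, the number of
#' distinct cell lines hit in either technology -- the summary consistency
#' metric.
#'
#' @param hits a [hit_matrix()] (or logical matrix with a `conditions`
#'   attribute annotating every column with cell_line, treatment,
#'   technology).
#' @return data.frame with columns `gene`, `ko_n_conditions_hit`,
#'   `ko_n_cell_lines_hit`, `ko_n_treatments_hit`, `act_n_conditions_hit`,
#'   `act_n_cell_lines_hit`, `act_n_treatments_hit`, `full_screen`.
#' @export
consistency_features <- function(hits) {
  conds <- attr(hits, "conditions")
  if (is.null(conds)) {
    stop("hit matrix lacks the 'conditions' column annotation")
  }
  need <- c("label", "cell_line", "treatment", "technology")
  if (!all(need %in% names(conds))) {
    stop("condition annotation needs columns label, cell_line, treatment, technology")
  }
  conds <- conds[match(colnames(hits), conds$label), ]
  if (anyNA(conds$technology)) {
    stop("every hit-matrix column must carry a technology annotation")
  }
  genes <- rownames(hits)
  per_tech <- function(tech) {
    sel <- conds$technology == tech
    sub <- hits[, sel, drop = FALSE]
    n_cond <- as.integer(rowSums(sub))
    n_cl <- apply(sub, 1L, function(h) length(unique(conds$cell_line[sel][h])))
    n_tr <- apply(sub, 1L, function(h) length(unique(conds$treatment[sel][h])))
    data.frame(n_conditions = n_cond, n_cell_lines = as.integer(n_cl),
               n_treatments = as.integer(n_tr))
  }
  ko <- per_tech("KO")
  act <- per_tech("activation")
  full <- apply(hits, 1L, function(h) length(unique(conds$cell_line[h])))
  data.frame(gene = genes,
             ko_n_conditions_hit = ko$n_conditions,
             ko_n_cell_lines_hit = ko$n_cell_lines,
             ko_n_treatments_hit = ko$n_treatments,
             act_n_conditions_hit = act$n_conditions,
             act_n_cell_lines_hit = act$n_cell_lines,
             act_n_treatments_hit = act$n_treatments,
             full_screen = as.integer(full),
             row.names = NULL)
}
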