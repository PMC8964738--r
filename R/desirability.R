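#' Per-gene statistics for one screen comparison
#'
#' Holds the MAGeCK/BAGEL-style per-gene output of one pairwise comparison of
#' screen arms -- Control vs Treated (CvT), Control vs Plasmid (CvP) or
#' Treated vs Plasmid (TvP) -- in one cell line x treatment x technology
#' condition. Essentiality flags arrive precomputed from the upstream screen
#' analysis (e.g. BAGEL at 5% FDR); this package consumes them, it does not
#' call essentiality from guide counts.
#'
#' @param genes character vector of unique gene identifiers.
#' @param lfc finite log2 fold-changes, one per gene.
#' @param pvalue p-values in \[0, 1\].
#' @param fdr false-discovery rates in \[0, 1\].
#' @param essential_flag logical, was the gene called essential in this
#'   comparison; recycled.
#' @param comparison `"CvT"`, `"CvP"` or `"TvP"`.
#' @param cell_line,treatment,technology condition metadata; `technology` is
#'   `"KO"` (CRISPRn loss-of-function) or `"activation"` (CRISPRa).
#' @return A data.frame of class `screen_comparison` with attributes
#'   `comparison` and `condition`.
#' @export
screen_comparison <- function(genes, lfc, pvalue, fdr, essential_flag = FALSE,
                              comparison = c("CvT", "CvP", "TvP"),
                              cell_line = "unknown", treatment = "unknown",
                              technology = c("KO", "activation")) {
  comparison <- match.arg(comparison)
  technology <- match.arg(technology)
  genes <- as.character(genes)
  n <- length(genes)
  stopifnot(length(lfc) == n, length(pvalue) == n, length(fdr) == n)
  if (anyDuplicated(genes)) stop("one row per gene: duplicated gene identifiers")
  if (any(!is.finite(lfc))) stop("lfc must be finite")
  if (any(pvalue < 0 | pvalue > 1)) stop("pvalue must lie in [0, 1]")
  if (any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  df <- data.frame(gene = genes, lfc = lfc, pvalue = pvalue, fdr = fdr,
                   essential_flag = rep_len(as.logical(essential_flag), n))
  structure(df, comparison = comparison,
            condition = list(cell_line = as.character(cell_line),
                             treatment = as.character(treatment),
                             technology = technology),
            class = c("screen_comparison", "data.frame"))
}

condition_label <- function(cond) {
  paste(cond$cell_line, cond$treatment, cond$technology, sep = "|")
}

#' FDR partial desirability
#'
#' A hard gate on statistical significance: 0 for FDR above 0.1, 1 otherwise.
#' An FDR of exactly 0.1 is treated as significant (ties break towards the
#' favourable branch). Because the overall desirability is a geometric mean,
#' the zero branch removes non-significant genes from consideration entirely.
#'
#' @param fdr numeric vector of false-discovery rates in \[0, 1\].
#' @param cutoff significance cut-off (default 0.1).
#' @return numeric vector of 0/1 desirabilities.
#' @export
#' @examples
#' d_fdr(c(0.2, 0.05, 0.1))
d_fdr <- function(fdr, cutoff = 0.1) {
  if (any(!is.finite(fdr)) || any(fdr < 0 | fdr > 1)) {
    stop("fdr must lie in [0, 1]")
  }
  as.numeric(fdr <= cutoff)
}

#' p-value partial desirability
#'
#' Maps a p-value to \[0.01, 1\]: 0.01 above `p_floor` (default 0.1), 1 at or
#' below `p_ceiling` (default 1e-4), and in between a power curve on the
#' -log10 axis,
#' `d = 0.01 + 0.99 * t^shape` with
#' `t = (log10(p_floor) - log10(p)) / (log10(p_floor) - log10(p_ceiling))`.
#' Larger `shape` makes the rise towards 1 faster near the ceiling. The floor
#' of 0.01 (rather than 0) keeps a marginal p-value from annihilating the
#' geometric-mean aggregate the way a failed FDR gate does.
#'
#' @param p numeric vector of p-values in (0, 1\]; exact zeros must be floored
#'   upstream (e.g. to half the smallest representable p of the screen tool).
#' @param shape curve exponent >= 1 (default 2).
#' @param p_floor,p_ceiling interpolation end points.
#' @return numeric vector of desirabilities in \[0.01, 1\].
#' @export
#' @examples
#' d_pvalue(c(0.5, 1e-4, 10^-2.5))
d_pvalue <- function(p, shape = 2, p_floor = 0.1, p_ceiling = 1e-4) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]; floor exact zeros upstream")
  }
  if (shape < 1) stop("shape must be >= 1")
  t <- (log10(p_floor) - log10(p)) / (log10(p_floor) - log10(p_ceiling))
  t <- pmin(pmax(t, 0), 1)
  d <- 0.01 + 0.99 * t^shape
  d[p > p_floor] <- 0.01
  d[p <= p_ceiling] <- 1
  d
}

#' Distribution-derived effect-size boundary
#'
#' The resistance boundary is `mean(lfc) + 3 * sd(lfc)`; the sensitivity
#' boundary is `mean(lfc) - 3 * sd(lfc)`. The sample (n-1) standard deviation
#' is used. With a degenerate (constant) LFC vector the boundary collapses to
#' the common value.
#'
#' @param lfcs numeric vector of log2 fold-changes (>= 2 finite values).
#' @param mode `"resistance"` or `"sensitivity"`.
#' @param k number of standard deviations (default 3).
#' @return scalar boundary on the log2 fold-change scale.
#' @export
#' @examples
#' lfc_boundary(c(-1, 0, 1))                  # 3
#' lfc_boundary(c(-1, 0, 1), "sensitivity")   # -3
lfc_boundary <- function(lfcs, mode = c("resistance", "sensitivity"), k = 3) {
  mode <- match.arg(mode)
  lfcs <- lfcs[is.finite(lfcs)]
  if (length(lfcs) < 2L) stop("need at least 2 finite log fold-changes")
  s <- stats::sd(lfcs)
  if (mode == "resistance") mean(lfcs) + k * s else mean(lfcs) - k * s
}

#' Effect-size partial desirability
#'
#' A step at the distribution-derived boundary: 1 on the favourable side
#' (at or above the boundary for resistance, at or below for sensitivity),
#' 0.01 on the other. Values exactly on the boundary take the favourable
#' branch. A smoothed logistic alternative is available via `smooth = TRUE`,
#' with `steepness` controlling the transition width (in LFC units).
#'
#' @param lfc numeric vector of log2 fold-changes.
#' @param boundary scalar boundary from [lfc_boundary()].
#' @param mode `"resistance"` or `"sensitivity"`.
#' @param smooth logical; replace the step with a logistic curve scaled to
#'   \[0.01, 1\].
#' @param steepness logistic scale parameter (default 0.1 LFC units).
#' @return numeric vector of desirabilities in \[0.01, 1\].
#' @export
d_lfc <- function(lfc, boundary, mode = c("resistance", "sensitivity"),
                  smooth = FALSE, steepness = 0.1) {
  mode <- match.arg(mode)
  if (any(!is.finite(lfc)) || !is.finite(boundary)) {
    stop("lfc and boundary must be finite")
  }
  delta <- if (mode == "resistance") lfc - boundary else boundary - lfc
  if (smooth) {
    0.01 + 0.99 / (1 + exp(-delta / steepness))
  } else {
    ifelse(delta >= 0, 1, 0.01)
  }
}

#' Essentiality partial desirability (resistance mode)
#'
#' Filters false-positive "resistance" calls that arise when knocking out a
#' slow essential gene makes treated cells die less quickly than control
#' cells: desirability is 0 when the gene was called essential in both the
#' CvP and CvT comparisons, or when its CvT log fold-change is negative;
#' otherwise 1.
#'
#' @param cvp_essential,cvt_essential logical essentiality calls from the
#'   upstream analysis for CvP and CvT.
#' @param cvt_lfc CvT log2 fold-change.
#' @return numeric vector of 0/1 desirabilities.
#' @export
d_essentiality <- function(cvp_essential, cvt_essential, cvt_lfc) {
  n <- max(length(cvp_essential), length(cvt_essential), length(cvt_lfc))
  cvp_essential <- rep_len(as.logical(cvp_essential), n)
  cvt_essential <- rep_len(as.logical(cvt_essential), n)
  cvt_lfc <- rep_len(cvt_lfc, n)
  as.numeric(!((cvp_essential & cvt_essential) | cvt_lfc < 0))
}

#' Aggregate partial desirabilities
#'
#' Weighted geometric mean, `(prod d_i^w_i)^(1/sum(w))`. Any zero component
#' forces the aggregate to zero, so hard gates (FDR, essentiality) veto a
#' gene outright while soft components (p-value, LFC floored at 0.01) only
#' attenuate it.
#'
#' @param components numeric vector (or matrix, aggregated row-wise) of
#'   desirabilities in \[0, 1\].
#' @param weights positive weights, one per component; equal by default.
#' @return scalar (or per-row vector) overall desirability in \[0, 1\].
#' @export
#' @examples
#' aggregate_desirability(c(0.25, 1))   # 0.5
#' aggregate_desirability(c(0.9, 0, 0.8))  # 0
aggregate_desirability <- function(components, weights = NULL) {
  if (is.matrix(components)) {
    return(apply(components, 1L, aggregate_desirability, weights = weights))
  }
  if (any(!is.finite(components)) ||
      any(components < 0) || any(components > 1)) {
    stop("desirability components must lie in [0, 1]")
  }
  if (is.null(weights)) weights <- rep(1, length(components))
  if (length(weights) != length(components)) {
    stop("weights and components must have the same length")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(components == 0)) return(0)
  exp(sum(weights * log(components)) / sum(weights))
}

#' Overall desirability of genes in one screen condition
#'
#' Combines the CvT and CvP comparisons of one condition into one score per
#' gene. In resistance mode four partial desirabilities are aggregated with
#' equal weights: the CvT FDR gate ([d_fdr()]), the CvT p-value curve
#' ([d_pvalue()]), the CvT effect-size step against the mean + 3 SD boundary
#' ([d_lfc()]), and the essentiality filter ([d_essentiality()]). In
#' sensitivity mode the essentiality filter is dropped and the effect-size
#' rule flips to the mean - 3 SD boundary. The LFC boundary is always
#' computed from the full CvT LFC distribution, not the joined subset.
#'
#' @param cvt,cvp [screen_comparison()] tables for the CvT and CvP
#'   comparisons of the same condition. Gene universes are inner-joined with
#'   a warning when they differ.
#' @param mode `"resistance"` or `"sensitivity"`.
#' @param shape p-value curve exponent, see [d_pvalue()].
#' @param weights optional component weights (resistance: fdr, pvalue, lfc,
#'   essentiality; sensitivity: fdr, pvalue, lfc).
#' @return A data.frame of class `desirability_result` with columns `gene`,
#'   `d_fdr`, `d_pvalue`, `d_lfc`, `d_essentiality` (NA in sensitivity mode)
#'   and `overall`, plus attributes `mode` and `condition`.
#' @export
overall_desirability <- function(cvt, cvp, mode = c("resistance", "sensitivity"),
                                 shape = 2, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cvt, "screen_comparison"),
            inherits(cvp, "screen_comparison"))
  common <- intersect(cvt$gene, cvp$gene)
  if (!length(common)) stop("CvT and CvP share no genes")
  if (length(common) < max(nrow(cvt), nrow(cvp))) {
    warning(sprintf("CvT and CvP gene universes differ; using %d shared genes",
                    length(common)))
  }
  boundary <- lfc_boundary(cvt$lfc, mode = mode)
  it <- cvt[match(common, cvt$gene), ]
  ip <- cvp[match(common, cvp$gene), ]
  p_eval <- pmax(it$pvalue, .Machine$double.xmin)  # guard exact zeros
  comp <- cbind(d_fdr = d_fdr(it$fdr),
                d_pvalue = d_pvalue(p_eval, shape = shape),
                d_lfc = d_lfc(it$lfc, boundary, mode = mode))
  d_ess <- rep(NA_real_, length(common))
  if (mode == "resistance") {
    d_ess <- d_essentiality(ip$essential_flag, it$essential_flag, it$lfc)
    comp <- cbind(comp, d_essentiality = d_ess)
  }
  overall <- aggregate_desirability(comp, weights = weights)
  structure(data.frame(gene = common,
                       d_fdr = comp[, "d_fdr"],
                       d_pvalue = comp[, "d_pvalue"],
                       d_lfc = comp[, "d_lfc"],
                       d_essentiality = d_ess,
                       overall = overall,
                       row.names = NULL),
            mode = mode, boundary = boundary,
            condition = attr(cvt, "condition"),
            class = c("desirability_result", "data.frame"))
}

#' Call screen hits
#'
#' A gene is a hit in a condition when its overall desirability exceeds 0.7
#' and its CvT positive-selection FDR is below 0.1 (both strict, as the
#' thresholds are stated).
#'
#' @param overall_desi overall desirability in \[0, 1\].
#' @param pos_fdr positive-selection FDR in \[0, 1\].
#' @param desi_cutoff,fdr_cutoff thresholds (defaults 0.7 and 0.1).
#' @return logical vector of hit calls.
#' @export
#' @examples
#' call_hit(c(0.8, 0.7, 0.9), c(0.05, 0.05, 0.1))
call_hit <- function(overall_desi, pos_fdr, desi_cutoff = 0.7,
                     fdr_cutoff = 0.1) {
  if (any(overall_desi < 0 | overall_desi > 1, na.rm = TRUE) ||
      any(pos_fdr < 0 | pos_fdr > 1, na.rm = TRUE)) {
    stop("inputs must lie in [0, 1]")
  }
  overall_desi > desi_cutoff & pos_fdr < fdr_cutoff
}
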