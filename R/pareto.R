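# Direction-correct a value matrix so that every objective is "maximize".
orient_matrix <- function(values, directions) {
  values <- as.matrix(values)
  if (ncol(values) != length(directions)) {
    stop("number of objectives and directions differ")
  }
  sign <- ifelse(directions == "maximize", 1, -1)
  sweep(values, 2L, sign, "*")
}

#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` when, after correcting for each objective's direction,
#' `a` is at least as good on every objective and strictly better on at
#' least one. Dominance is irreflexive (a vector never dominates itself) and
#' transitive; two vectors can be mutually incomparable.
#'
#' @param a,b numeric vectors of equal length, aligned to `directions`.
#' @param directions character vector of `"maximize"` / `"minimize"`, one
#'   per objective.
#' @return logical scalar.
#' @export
#' @examples
#' dominates(c(2, 3), c(1, 3), c("maximize", "maximize"))  # TRUE
dominates <- function(a, b, directions) {
  if (length(a) != length(b) || length(a) != length(directions)) {
    stop("objective vectors and directions must have equal length")
  }
  sgn <- ifelse(directions == "maximize", 1, -1)
  a <- a * sgn; b <- b * sgn
  all(a >= b) && any(a > b)
}

# Logical mask of dominated rows in an oriented (all-maximize) matrix.
# A dominated row cannot dominate anything its dominator does not, so rows
# already marked dominated are skipped as probes.
dominated_mask <- function(m) {
  n <- nrow(m)
  dom <- logical(n)
  for (i in seq_len(n)) {
    if (dom[i]) next
    le <- m <= rep(m[i, ], each = n)
    lt <- m < rep(m[i, ], each = n)
    covered <- rowSums(le) == ncol(m) & rowSums(lt) > 0L
    dom[covered] <- TRUE
  }
  dom
}

#' Extract the Pareto front
#'
#' The maximal set of mutually non-dominated solutions: no other row is at
#' least as good everywhere and strictly better somewhere. Ties (identical
#' rows) are mutually non-dominating and therefore share the front.
#'
#' @param values numeric matrix (rows = solutions, columns = objectives) or
#'   data.frame; all values must be finite.
#' @param directions `"maximize"` / `"minimize"` per column, recycled.
#' @return integer vector of row indices on the front.
#' @export
pareto_front <- function(values, directions = "maximize") {
  values <- as.matrix(values)
  if (!nrow(values)) stop("no solutions to rank")
  if (any(!is.finite(values))) stop("objective values must be finite")
  directions <- rep_len(directions, ncol(values))
  m <- orient_matrix(values, directions)
  which(!dominated_mask(m))
}

#' Non-dominated sorting into Pareto levels
#'
#' Iterative front peeling: level 1 is the Pareto front of all solutions,
#' level L the front of what remains after removing levels 1..L-1. Every
#' solution receives exactly one level; level-1 membership is non-empty for
#' non-empty input.
#'
#' @inheritParams pareto_front
#' @return integer vector of Pareto levels (>= 1), one per row.
#' @export
pareto_levels <- function(values, directions = "maximize") {
  values <- as.matrix(values)
  if (!nrow(values)) stop("no solutions to rank")
  if (any(!is.finite(values))) stop("objective values must be finite")
  directions <- rep_len(directions, ncol(values))
  m <- orient_matrix(values, directions)
  lev <- integer(nrow(m))
  remaining <- seq_len(nrow(m))
  l <- 0L
  while (length(remaining)) {
    l <- l + 1L
    on_front <- !dominated_mask(m[remaining, , drop = FALSE])
    lev[remaining[on_front]] <- l
    remaining <- remaining[!on_front]
  }
  lev
}

#' Rank genes of a feature table by a preference
#'
#' The core re-ranking step: the preference's objectives are pulled out of
#' the feature table, genes are non-dominated sorted into Pareto levels, and
#' the result is ordered deterministically by (level, optional sort-within
#' features in direction-corrected descending order, gene id). Genes missing
#' any selected objective are excluded with a warning (dominance is
#' undefined on missing coordinates) or, with
#' `missing = "impute_worst"`, assigned the worst observed value of each
#' missing objective so they can still be ranked (conservatively).
#'
#' @param table a [feature_table()]
#' @param pref a [preference()]; every objective must exist in `table`.
#' @param sort_within optional character vector of features used to order
#'   genes inside a Pareto level; directions are taken from the preference
#'   when the feature is an objective, else "maximize".
#' @param missing `"exclude"` (default) or `"impute_worst"`.
#' @return data.frame of class `ranked_genes` with columns `gene`,
#'   `pareto_level` and the objective columns, ordered as described;
#'   attributes `preference`, `excluded` (data.frame of gene/reason) and
#'   `missing_policy`.
#' @export
rank_genes <- function(table, pref, sort_within = NULL,
                       missing = c("exclude", "impute_worst")) {
  missing <- match.arg(missing)
  validate_preference(pref, table)
  feats <- pref$objectives$feature
  dirs <- pref$objectives$direction
  m <- as.matrix(as.data.frame(table)[, feats, drop = FALSE])
  rownames(m) <- table$gene
  excluded <- data.frame(gene = character(0), reason = character(0))
  if (missing == "impute_worst") {
    for (j in seq_along(feats)) {
      col <- m[, j]
      if (anyNA(col)) {
        worst <- if (dirs[j] == "maximize") {
          min(col, na.rm = TRUE)
        } else {
          max(col, na.rm = TRUE)
        }
        m[is.na(col), j] <- worst
      }
    }
  }
  incomplete <- rowSums(is.na(m)) > 0L
  if (any(incomplete)) {
    bad_feat <- apply(is.na(m[incomplete, , drop = FALSE]), 1L, function(z) {
      paste("missing", paste(feats[z], collapse = ","))
    })
    excluded <- data.frame(gene = rownames(m)[incomplete], reason = bad_feat,
                           row.names = NULL)
    warning(sprintf("%d gene(s) excluded from ranking (missing objectives)",
                    sum(incomplete)))
    m <- m[!incomplete, , drop = FALSE]
  }
  if (!nrow(m)) stop("no gene has complete values for the selected objectives")
  lev <- pareto_levels(m, dirs)
  out <- data.frame(gene = rownames(m), pareto_level = lev,
                    as.data.frame(m), check.names = FALSE, row.names = NULL)
  ord_cols <- list(out$pareto_level)
  if (!is.null(sort_within)) {
    bad <- setdiff(sort_within, names(out))
    if (length(bad)) {
      stop(sprintf("sort_within feature(s) not among the objectives: %s",
                   paste(bad, collapse = ", ")))
    }
    for (sw in sort_within) {
      dir <- dirs[match(sw, feats)]
      if (is.na(dir)) dir <- "maximize"
      ord_cols <- c(ord_cols,
                    list(if (dir == "maximize") -out[[sw]] else out[[sw]]))
    }
  }
  ord_cols <- c(ord_cols, list(out$gene))
  out <- out[do.call(order, ord_cols), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, preference = pref, excluded = excluded,
            missing_policy = missing,
            class = c("ranked_genes", "data.frame"))
}

#' @export
print.ranked_genes <- function(x, ...) {
  pref <- attr(x, "preference")
  cat(sprintf("<ranked_genes> %d genes, %d Pareto level(s), preference '%s'\n",
              nrow(x), max(x$pareto_level), pref$name))
  cat(sprintf("level 1 holds %d gene(s)\n", sum(x$pareto_level == 1L)))
  NextMethod()
}

#' Write a ranking and its provenance
#'
#' Emits the ranked table as TSV and a JSON provenance block describing the
#' preference applied, the missing-value policy, excluded genes and the
#' package version, so any ranking can be reproduced from its inputs.
#'
#' @param ranked a [rank_genes()] result.
#' @param path output TSV path.
#' @param provenance_path optional JSON path (default: `path` with a
#'   `.provenance.json` suffix).
#' @return `path`, invisibly.
#' @export
write_ranked <- function(ranked, path, provenance_path = NULL) {
  stopifnot(inherits(ranked, "ranked_genes"))
  write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  if (is.null(provenance_path)) {
    provenance_path <- paste0(sub("\\.tsv$", "", path), ".provenance.json")
  }
  pref <- attr(ranked, "preference")
  prov <- list(
    preference = list(name = pref$name,
                      objectives = pref$objectives),
    missing_policy = attr(ranked, "missing_policy"),
    excluded_genes = attr(ranked, "excluded"),
    n_ranked = nrow(ranked),
    n_level1 = sum(ranked$pareto_level == 1L),
    package = "crisprank",
    version = as.character(utils::packageVersion("crisprank")))
  jsonlite::write_json(prov, provenance_path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' External benchmark against a published feature table
#'
#' The study this framework emulates reports a 57-gene recommended list
#' computed from its own (externally hosted) feature table and default
#' preference. That table is not shipped here; given a local copy of it (and
#' optionally the matching preference file), this helper re-runs the ranking
#' and returns the level-1 genes so the published list can be compared
#' offline.
#'
#' @param feature_path path to the downloaded feature TSV (gene column
#'   first).
#' @param preference_path optional preference YAML/JSON; defaults to
#'   [default_preference()].
#' @param dialect feature file dialect, `"tsv"` or `"csv"`.
#' @return character vector of level-1 genes.
#' @export
external_benchmark <- function(feature_path, preference_path = NULL,
                               dialect = "tsv") {
  if (!file.exists(feature_path)) {
    stop(sprintf(paste0(
      "external benchmark input not found: %s\n",
      "download the published hybrid feature table and pass its local path; ",
      "this benchmark is optional and requires external data"), feature_path))
  }
  table <- read_feature_table(feature_path, dialect = dialect)
  pref <- if (is.null(preference_path)) {
    default_preference()
  } else {
    read_preference(preference_path)
  }
  ranked <- rank_genes(table, pref)
  ranked$gene[ranked$pareto_level == 1L]
}
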