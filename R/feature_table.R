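#' Construct a gene-by-feature table
#'
#' The feature table is the decision-variable space of the re-ranking problem:
#' one row per gene, one numeric column per evidence feature (objective).
#' Missing values are allowed and represent evidence that is unavailable for a
#' gene; how they are handled at ranking time is decided by [rank_genes()].
#'
#' @param df data.frame whose first column, named `"gene"`, holds unique,
#'   non-empty gene identifiers; all remaining columns must be numeric.
#' @param meta optional data.frame with columns `feature`, `category`,
#'   `description` annotating feature provenance. `category` must be one of
#'   `"crispr"`, `"graph"`, `"literature"`, `"clinical"`, `"preclinical"`,
#'   `"tractability"`, `"essentiality"`.
#' @return An object of class `feature_table` (a data.frame with a
#'   `feature_meta` attribute).
#' @seealso [read_feature_table()], [write_feature_table()], [rank_genes()]
#' @export
#' @examples
#' ft <- feature_table(data.frame(gene = c("EGFR", "MET"),
#'                                pagerank = c(0.4, 0.1)))
#' feature_names(ft)
feature_table <- function(df, meta = NULL) {
  stopifnot(is.data.frame(df))
  if (ncol(df) < 1L || names(df)[1L] != "gene") {
    stop("first column of a feature table must be named 'gene'")
  }
  df$gene <- as.character(df$gene)
  if (anyNA(df$gene) || any(!nzchar(df$gene))) {
    stop("gene identifiers must be non-empty")
  }
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) {
    stop(sprintf("duplicated gene identifier(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  feats <- setdiff(names(df), "gene")
  if (anyDuplicated(feats)) stop("feature names must be unique")
  for (f in feats) {
    if (!is.numeric(df[[f]])) {
      stop(sprintf("feature column '%s' is not numeric", f))
    }
  }
  if (!is.null(meta)) meta <- validate_feature_meta(meta, feats)
  structure(df, feature_meta = meta,
            class = c("feature_table", "data.frame"))
}

feature_categories <- c("crispr", "graph", "literature", "clinical",
                        "preclinical", "tractability", "essentiality")

validate_feature_meta <- function(meta, feats) {
  stopifnot(is.data.frame(meta))
  need <- c("feature", "category", "description")
  if (!all(need %in% names(meta))) {
    stop("feature metadata needs columns feature, category, description")
  }
  bad <- setdiff(meta$category, feature_categories)
  if (length(bad)) {
    stop(sprintf("unknown feature category: %s", paste(bad, collapse = ", ")))
  }
  extra <- setdiff(meta$feature, feats)
  if (length(extra)) {
    stop(sprintf("metadata for unknown feature(s): %s",
                 paste(extra, collapse = ", ")))
  }
  meta[, need]
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d genes x %d features\n",
              nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Feature names of a feature table
#' @param table a [feature_table()]
#' @return character vector of feature (objective) column names.
#' @export
feature_names <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  setdiff(names(table), "gene")
}

#' Read a gene-by-feature table from TSV/CSV
#'
#' Expects a header row with a leading `gene` column; every other column is
#' parsed as numeric with empty cells treated as missing. Parsing is strict:
#' duplicated genes and non-numeric cells are hard errors that name the
#' offending gene or cell, so silent coercion can never corrupt a ranking.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
  if (ncol(raw) < 1L || names(raw)[1L] != "gene") {
    stop(sprintf("%s: first column must be named 'gene'", path))
  }
  dup <- raw$gene[duplicated(raw$gene)]
  if (length(dup)) {
    stop(sprintf("%s: duplicated gene '%s'", path, dup[[1L]]))
  }
  for (f in setdiff(names(raw), "gene")) {
    cell <- raw[[f]]
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                   path, cell[bad[[1L]]], f, bad[[1L]]))
    }
    raw[[f]] <- num
  }
  feature_table(raw)
}

#' Write a feature table to TSV
#'
#' Columns are written in their stored order with the gene column first;
#' missing values are rendered as empty strings so that
#' `read_feature_table(write_feature_table(x))` round-trips.
#'
#' @param table a [feature_table()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  write.table(table, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Construct an optimisation preference
#'
#' A preference is the vector objective function of the ranking problem: an
#' ordered set of feature names, each with an optimisation direction. Genes
#' are compared by Pareto dominance with respect to exactly these objectives.
#'
#' @param features character vector of objective (feature) names; must be
#'   non-empty and free of duplicates.
#' @param directions `"maximize"` or `"minimize"`, recycled to
#'   `length(features)`.
#' @param name short label for the preference.
#' @return An object of class `preference`: a list with elements `name` and
#'   `objectives` (data.frame with columns `feature`, `direction`).
#' @export
#' @examples
#' preference(c("pagerank", "RNASeq_pval"), c("maximize", "minimize"))
preference <- function(features, directions = "maximize", name = "custom") {
  features <- as.character(features)
  if (!length(features)) stop("a preference needs at least one objective")
  dup <- features[duplicated(features)]
  if (length(dup)) {
    stop(sprintf("objective(s) listed twice: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  directions <- rep_len(as.character(directions), length(features))
  bad <- setdiff(directions, c("maximize", "minimize"))
  if (length(bad)) {
    stop(sprintf("unknown direction '%s' (use 'maximize' or 'minimize')",
                 bad[[1L]]))
  }
  structure(list(name = as.character(name)[[1L]],
                 objectives = data.frame(feature = features,
                                         direction = directions)),
            class = "preference")
}

#' @export
print.preference <- function(x, ...) {
  cat(sprintf("<preference> '%s': %d objective(s)\n",
              x$name, nrow(x$objectives)))
  for (i in seq_len(nrow(x$objectives))) {
    cat(sprintf("  %-20s %s\n",
                x$objectives$feature[i], x$objectives$direction[i]))
  }
  invisible(x)
}

#' Read a preference from YAML or JSON
#'
#' The file must contain `name` and `objectives`, the latter a list of
#' `{feature, direction}` entries. `.json` files are parsed with jsonlite,
#' anything else with yaml (which also accepts JSON).
#'
#' @param path path to a YAML or JSON preference file.
#' @return A [preference()].
#' @export
read_preference <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$objectives) || !length(spec$objectives)) {
    stop(sprintf("%s: preference has an empty objective list", path))
  }
  feats <- vapply(spec$objectives, function(o) {
    if (is.null(o$feature)) stop(sprintf("%s: objective without 'feature'", path))
    as.character(o$feature)
  }, character(1))
  dirs <- vapply(spec$objectives, function(o) {
    if (is.null(o$direction)) "maximize" else as.character(o$direction)
  }, character(1))
  name <- if (is.null(spec$name)) "unnamed" else as.character(spec$name)
  preference(feats, dirs, name = name)
}

#' Write a preference to YAML
#' @param pref a [preference()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preference <- function(pref, path) {
  stopifnot(inherits(pref, "preference"))
  obj <- lapply(seq_len(nrow(pref$objectives)), function(i) {
    list(feature = pref$objectives$feature[i],
         direction = pref$objectives$direction[i])
  })
  yaml::write_yaml(list(name = pref$name, objectives = obj), path)
  invisible(path)
}

#' The shipped default preference
#'
#' Ten objectives spanning screen consistency, transcriptomic response,
#' trial-specific clinical enrichment, literature co-mention support and
#' network centrality. All objectives default to `maximize` under the
#' resistance framing; directions are meant to be overridden per analysis.
#'
#' @return A [preference()] with ten objectives.
#' @export
default_preference <- function() {
  preference(c("full_screen", "RNASeq_LFC",
               "clinical_ES1", "clinical_ES2", "clinical_ES3",
               "lit_EGFR", "lit_NSCLC",
               "pagerank", "betweenness", "RNASeq_pval"),
             "maximize", name = "default")
}

#' Check a preference against a feature table
#'
#' @param pref a [preference()]
#' @param table a [feature_table()]
#' @return `pref`, invisibly; errors listing the available features if any
#'   objective is absent from the table.
#' @export
validate_preference <- function(pref, table) {
  stopifnot(inherits(pref, "preference"), inherits(table, "feature_table"))
  missing <- setdiff(pref$objectives$feature, feature_names(table))
  if (length(missing)) {
    stop(sprintf(
      "objective(s) not present in the feature table: %s\navailable features: %s",
      paste(missing, collapse = ", "),
      paste(feature_names(table), collapse = ", ")))
  }
  invisible(pref)
}
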