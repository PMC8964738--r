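# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results from first principles (pairwise
# dominance matrices, exhaustive shortest-path enumeration, set intersection
# counting) so they share no code with the implementation they check.

# --- Pareto oracles ---------------------------------------------------------

# D[i, j] is TRUE iff row i dominates row j in an oriented (all-maximize)
# matrix: >= everywhere and > somewhere.
bf_dominance_matrix <- function(m) {
  n <- nrow(m)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(m))) {
    ge <- ge & outer(m[, k], m[, k], ">=")
    gt <- gt | outer(m[, k], m[, k], ">")
  }
  ge & gt
}

bf_front <- function(m) which(colSums(bf_dominance_matrix(m)) == 0L)

bf_levels <- function(m) {
  lev <- integer(nrow(m))
  remaining <- seq_len(nrow(m))
  l <- 0L
  while (length(remaining)) {
    l <- l + 1L
    fr <- bf_front(m[remaining, , drop = FALSE])
    lev[remaining[fr]] <- l
    remaining <- remaining[-fr]
  }
  lev
}

orient <- function(m, directions) {
  sweep(m, 2L, ifelse(directions == "maximize", 1, -1), "*")
}

# --- Betweenness oracle -----------------------------------------------------

bf_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ])) {
        if (!is.finite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# All shortest s-t paths, reconstructed backwards through BFS layers.
bf_shortest_paths <- function(adj, s, t) {
  d <- bf_bfs_dist(adj, s)
  if (!is.finite(d[t])) return(list())
  build <- function(v) {
    if (v == s) return(list(s))
    preds <- which(adj[v, ] & d == d[v] - 1)
    out <- list()
    for (p in preds) {
      for (path in build(p)) out <- c(out, list(c(path, v)))
    }
    out
  }
  build(t)
}

# Unnormalised betweenness, endpoints excluded, each unordered pair counted
# once (undirected convention).
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- bf_shortest_paths(adj, s, t)
      if (!length(paths)) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        b[idx] <- b[idx] + as.numeric(tab) / length(paths)
      }
    }
  }
  b
}

random_undirected_adj <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

kg_from_adj <- function(adj, relation = "interacts") {
  ids <- paste0("n", seq_len(nrow(adj)))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  knowledge_graph(
    data.frame(source = ids[idx[, 1]], relation = relation,
               target = ids[idx[, 2]]),
    nodes = data.frame(id = ids, type = "gene"))
}

# --- Small screen fixtures --------------------------------------------------

toy_comparison <- function(genes, lfc, pvalue, fdr, essential = FALSE,
                           comparison = "CvT", cell_line = "PC-9",
                           treatment = "gefitinib", technology = "KO") {
  screen_comparison(genes, lfc, pvalue, fdr, essential,
                    comparison = comparison, cell_line = cell_line,
                    treatment = treatment, technology = technology)
}

# A hand-built hit matrix with explicit condition annotation.
toy_hit_matrix <- function(hits, cell_lines, treatments, technologies) {
  labels <- paste(cell_lines, treatments, technologies, sep = "|")
  colnames(hits) <- labels
  structure(hits,
            conditions = data.frame(label = labels, cell_line = cell_lines,
                                    treatment = treatments,
                                    technology = technologies),
            class = c("hit_matrix", class(hits)))
}

toy_corpus <- function() {
  lit_corpus(list(
    list(doc_id = "d1", year = 2005, mentions = c("A", "EGFR")),
    list(doc_id = "d2", year = 2010, mentions = c("A")),
    list(doc_id = "d3", year = 2015, mentions = c("A", "EGFR", "NSCLC"))))
}

random_corpus <- function(n_docs, entities, p = 0.3) {
  lit_corpus(lapply(seq_len(n_docs), function(d) {
    list(doc_id = paste0("d", d), year = sample(2000:2019, 1),
         mentions = entities[runif(length(entities)) < p])
  }))
}
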