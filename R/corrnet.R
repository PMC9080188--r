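#' Pearson correlation of one RNA pair
#'
#' Sample Pearson correlation with the two-sided p-value from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom;
#' `|r| = 1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @return List with `r`, `p_value` and `n`.
#' @export
pearson_edge <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("vectors differ in length (%d vs %d)", n, length(y))
  if (n < 3L) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  list(r = r, p_value = cor_p(r, n), n = n)
}

# two-sided p of a Pearson r at sample size n (t transform)
cor_p <- function(r, n) {
  p <- numeric(length(r))
  one <- 1 - r^2 <= .Machine$double.eps * 4
  p[one] <- 0
  t <- abs(r[!one]) * sqrt(n - 2) / sqrt(1 - r[!one]^2)
  p[!one] <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p
}

#' Build the co-expression network over candidate RNAs
#'
#' Computes the Pearson correlation of every unordered candidate pair over the
#' chosen sample set and keeps as edges exactly the pairs with `r > r_min` and
#' `p < p_max` (both strict; with `use_abs = TRUE` the magnitude `|r|` is
#' gated instead). Zero-degree nodes are then removed and the remaining graph
#' is partitioned into modules (connected components).
#'
#' Candidate genes that are constant over the chosen samples have no defined
#' correlation; they are dropped with a warning.
#'
#' @param x an [expr_matrix].
#' @param candidates character vector of candidate gene ids (subset of the
#'   matrix genes), at least 2.
#' @param r_min,p_max edge gates; defaults 0.85 and 0.05.
#' @param sample_set `"all"` (default: tumor + normal), `"tumor"` or
#'   `"normal"` - the columns the correlations are computed over.
#' @param use_abs gate on `|r|` instead of signed `r`.
#' @return An object of class `corr_network`: list with
#'   `nodes` (data.frame `gene_id`, `role`, `degree`, `module`),
#'   `edges` (data.frame `node_a`, `node_b`, `r`, `p_value`, `n`) and the
#'   gating parameters. Node pairs are stored with `node_a < node_b`.
#' @export
build_network <- function(x, candidates, r_min = 0.85, p_max = 0.05,
                          sample_set = c("all", "tumor", "normal"),
                          use_abs = FALSE) {
  sample_set <- match.arg(sample_set)
  stopifnot(inherits(x, "expr_matrix"))
  if (length(candidates) < 2L) stopf("need at least 2 candidate genes")
  missing <- setdiff(candidates, rownames(x$values))
  if (length(missing)) stopf("candidates not in matrix: %s",
                             paste(missing, collapse = ", "))
  cols <- switch(sample_set,
                 all = colnames(x$values),
                 tumor = names(x$group)[x$group == "tumor"],
                 normal = names(x$group)[x$group == "normal"])
  if (length(cols) < 3L) stopf("need at least 3 samples to correlate")
  v <- x$values[candidates, cols, drop = FALSE]
  const <- apply(v, 1L, stats::sd) == 0
  if (any(const)) {
    warnf("dropping %d constant candidate gene(s): %s", sum(const),
          paste(candidates[const], collapse = ", "))
    v <- v[!const, , drop = FALSE]
    candidates <- candidates[!const]
    if (length(candidates) < 2L) stopf("fewer than 2 usable candidates")
  }
  n <- ncol(v)
  R <- stats::cor(t(v))
  crit <- if (use_abs) abs(R) else R
  idx <- which(upper.tri(R) & crit > r_min, arr.ind = TRUE)
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      r = numeric(0), p_value = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(idx)) {
    r <- R[idx]
    p <- cor_p(r, n)
    keep <- p < p_max
    if (any(keep)) {
      a <- candidates[idx[keep, 1L]]
      b <- candidates[idx[keep, 2L]]
      edges <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b),
                          r = r[keep], p_value = p[keep], n = n,
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  node_ids <- sort(unique(c(edges$node_a, edges$node_b)))  # prune degree 0
  deg <- table(factor(c(edges$node_a, edges$node_b), levels = node_ids))
  modules <- find_modules(edges)
  nodes <- data.frame(gene_id = node_ids,
                      role = unname(x$role[node_ids]),
                      degree = as.integer(deg[node_ids]),
                      module = unname(modules[node_ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 r_min = r_min, p_max = p_max, use_abs = use_abs,
                 sample_set = sample_set, n_samples = n),
            class = "corr_network")
}

#' Partition a network into modules (connected components)
#'
#' Module labels are deterministic: components are numbered by decreasing
#' size, ties broken by their lexicographically smallest member id.
#'
#' @param net a `corr_network`, or an edge data.frame with columns
#'   `node_a`/`node_b`.
#' @return Named integer vector: module id per node.
#' @export
find_modules <- function(net) {
  edges <- if (inherits(net, "corr_network")) net$edges else net
  if (nrow(edges) == 0L) return(stats::setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  first <- vapply(seq_len(comp$no),
                  function(k) min(names(memb)[memb == k]), character(1))
  ord <- order(-comp$csize, first)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  out <- stats::setNames(relabel[memb], names(memb))
  out[order(names(out))]
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network: %d nodes (%d lncRNA, %d mRNA), %d edges, %d module(s)\n",
              nrow(x$nodes), sum(x$nodes$role == "lncRNA"),
              sum(x$nodes$role == "mRNA"), nrow(x$edges),
              if (nrow(x$nodes)) max(x$nodes$module) else 0L))
  cat(sprintf("  gates: %s > %g, p < %g over %d %s sample(s)\n",
              if (x$use_abs) "|r|" else "r", x$r_min, x$p_max,
              x$n_samples, x$sample_set))
  invisible(x)
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                directed = FALSE,
                                vertices = net$nodes$gene_id)
}

#' Export network node and edge tables
#'
#' Writes the edge list (`node_a`, `node_b`, `r`, `p_value`, `n`) and node
#' table (`gene_id`, `role`, `degree`, `module`) as TSV consumable by
#' Cytoscape-class viewers; optionally a GraphML file.
#'
#' @param net a `corr_network`.
#' @param edge_path,node_path output TSV paths (`NULL` to skip).
#' @param graphml_path optional GraphML output path.
#' @param header_line optional `#` provenance line.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, edge_path = NULL, node_path = NULL,
                          graphml_path = NULL, header_line = NULL) {
  stopifnot(inherits(net, "corr_network"))
  written <- character(0)
  if (!is.null(edge_path))
    written <- c(written, write_tsv(net$edges, edge_path, header_line))
  if (!is.null(node_path))
    written <- c(written, write_tsv(net$nodes, node_path, header_line))
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
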