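# lncRNA -> mRNA -> GO term -> cancer hallmark tripartite chart and the
# path-count association rule. lncRNAs have no direct annotation; their
# hallmark associations are inherited through their network mRNA neighbors.

#' Build the lncRNA-mRNA-GO-hallmark chart
#'
#' Assembles a layered graph: lncRNA-mRNA edges come from the co-expression
#' network, mRNA-GO edges from the gene annotation table and GO-hallmark
#' edges from the mapping table. RNAs with no route to any hallmark are
#' dropped, as are GO terms with no hallmark. Annotation rows for genes
#' absent from the network are ignored (their count is recorded).
#'
#' @param net a `corr_network`.
#' @param gene_go data.frame with columns `gene_id`, `go_id`.
#' @param go_hallmark non-empty data.frame with columns `go_id`, `hallmark`.
#' @return Object of class `tripartite_chart`: edge data.frames `lnc_mrna`,
#'   `mrna_go`, `go_hallmark`, a named `module` vector for the retained RNA
#'   nodes, and drop counts.
#' @export
build_chart <- function(net, gene_go, go_hallmark) {
  stopifnot(inherits(net, "corr_network"))
  if (is.null(go_hallmark) || nrow(go_hallmark) == 0L)
    stopf("empty GO-to-hallmark table")
  for (nm in c("gene_id", "go_id"))
    if (is.null(gene_go[[nm]])) stopf("gene_go lacks column '%s'", nm)
  for (nm in c("go_id", "hallmark"))
    if (is.null(go_hallmark[[nm]])) stopf("go_hallmark lacks column '%s'", nm)
  gene_go <- unique(data.frame(gene_id = as.character(gene_go$gene_id),
                               go_id = as.character(gene_go$go_id),
                               stringsAsFactors = FALSE))
  go_hallmark <- unique(data.frame(go_id = as.character(go_hallmark$go_id),
                                   hallmark = as.character(go_hallmark$hallmark),
                                   stringsAsFactors = FALSE))
  roles <- stats::setNames(net$nodes$role, net$nodes$gene_id)
  modules <- stats::setNames(net$nodes$module, net$nodes$gene_id)
  e <- net$edges
  lnc_side_a <- roles[e$node_a] == "lncRNA" & roles[e$node_b] == "mRNA"
  lnc_side_b <- roles[e$node_b] == "lncRNA" & roles[e$node_a] == "mRNA"
  lnc_mrna <- rbind(
    data.frame(lncRNA = e$node_a[lnc_side_a], mRNA = e$node_b[lnc_side_a],
               stringsAsFactors = FALSE),
    data.frame(lncRNA = e$node_b[lnc_side_b], mRNA = e$node_a[lnc_side_b],
               stringsAsFactors = FALSE))
  net_mrnas <- net$nodes$gene_id[net$nodes$role == "mRNA"]
  n_ignored <- sum(!gene_go$gene_id %in% net_mrnas)
  mrna_go <- gene_go[gene_go$gene_id %in% net_mrnas, , drop = FALSE]
  # prune back from the hallmark layer
  go_ok <- intersect(mrna_go$go_id, go_hallmark$go_id)
  go_hallmark <- go_hallmark[go_hallmark$go_id %in% go_ok, , drop = FALSE]
  mrna_go <- mrna_go[mrna_go$go_id %in% go_ok, , drop = FALSE]
  mrna_ok <- unique(mrna_go$gene_id)
  lnc_mrna <- lnc_mrna[lnc_mrna$mRNA %in% mrna_ok, , drop = FALSE]
  mrna_keep <- intersect(mrna_ok, lnc_mrna$mRNA)
  mrna_go <- mrna_go[mrna_go$gene_id %in% mrna_keep, , drop = FALSE]
  go_keep <- unique(mrna_go$go_id)
  go_hallmark <- go_hallmark[go_hallmark$go_id %in% go_keep, , drop = FALSE]
  lnc_keep <- unique(lnc_mrna$lncRNA)
  rna_keep <- c(sort(lnc_keep), sort(mrna_keep))
  n_dropped <- nrow(net$nodes) - length(rna_keep)
  ord <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]; rownames(df) <- NULL; df
  }
  structure(list(lnc_mrna = ord(lnc_mrna), mrna_go = ord(mrna_go),
                 go_hallmark = ord(go_hallmark),
                 module = modules[rna_keep],
                 n_rna_dropped = n_dropped,
                 n_annotation_ignored = n_ignored),
            class = "tripartite_chart")
}

#' @export
print.tripartite_chart <- function(x, ...) {
  cat(sprintf("tripartite chart: %d lncRNA - %d mRNA - %d GO term - %d hallmark node(s)\n",
              length(unique(x$lnc_mrna$lncRNA)), length(unique(x$lnc_mrna$mRNA)),
              length(unique(x$mrna_go$go_id)), length(unique(x$go_hallmark$hallmark))))
  cat(sprintf("  edges: %d lncRNA-mRNA, %d mRNA-GO, %d GO-hallmark; %d RNA(s) dropped (no hallmark route), %d annotation row(s) ignored\n",
              nrow(x$lnc_mrna), nrow(x$mrna_go), nrow(x$go_hallmark),
              x$n_rna_dropped, x$n_annotation_ignored))
  invisible(x)
}

chart_lncrnas <- function(chart) sort(unique(chart$lnc_mrna$lncRNA))

#' Count lncRNA-to-hallmark paths
#'
#' For one lncRNA, counts for every hallmark the number of distinct
#' (mRNA neighbor, GO term) pairs lying on a lncRNA -> mRNA -> GO -> hallmark
#' route. This is the "degree from the specified lncRNA" used by the
#' association rule: an mRNA connecting through three different GO terms to
#' the same hallmark contributes 3.
#'
#' @param chart a [build_chart()] result.
#' @param lncrna a lncRNA id present in the chart.
#' @return Named integer vector (hallmark -> path count), descending; empty
#'   if the lncRNA reaches no hallmark.
#' @export
count_paths <- function(chart, lncrna) {
  stopifnot(inherits(chart, "tripartite_chart"))
  if (!lncrna %in% chart$lnc_mrna$lncRNA)
    stopf("unknown lncRNA: %s", lncrna)
  nb <- chart$lnc_mrna$mRNA[chart$lnc_mrna$lncRNA == lncrna]
  mg <- chart$mrna_go[chart$mrna_go$gene_id %in% nb, , drop = FALSE]
  if (nrow(mg) == 0L) return(stats::setNames(integer(0), character(0)))
  routes <- merge(mg, chart$go_hallmark, by = "go_id")
  if (nrow(routes) == 0L) return(stats::setNames(integer(0), character(0)))
  routes <- unique(routes[, c("gene_id", "go_id", "hallmark")])
  cnt <- table(routes$hallmark)
  out <- stats::setNames(as.integer(cnt), names(cnt))
  out[order(-out, names(out))]
}

#' Predict lncRNA-hallmark associations by the path-count rule
#'
#' One record per (lncRNA, hallmark) pair with at least one route; an
#' association is called strong when its path count strictly exceeds
#' `strong_min` (the "degree > 2" rule at the default).
#'
#' @param chart a [build_chart()] result.
#' @param strong_min strict threshold for the `strong` flag (default 2).
#' @return Data.frame: `lncRNA`, `hallmark`, `path_count`, `strong`,
#'   `witnesses` (semicolon-joined `mRNA|GO` pairs), sorted by descending
#'   path count.
#' @export
predict_associations <- function(chart, strong_min = 2) {
  stopifnot(inherits(chart, "tripartite_chart"))
  lncs <- chart_lncrnas(chart)
  rows <- list()
  for (l in lncs) {
    nb <- chart$lnc_mrna$mRNA[chart$lnc_mrna$lncRNA == l]
    mg <- chart$mrna_go[chart$mrna_go$gene_id %in% nb, , drop = FALSE]
    if (nrow(mg) == 0L) next
    routes <- unique(merge(mg, chart$go_hallmark, by = "go_id")[,
                     c("gene_id", "go_id", "hallmark")])
    if (nrow(routes) == 0L) next
    for (h in sort(unique(routes$hallmark))) {
      rh <- routes[routes$hallmark == h, , drop = FALSE]
      rh <- rh[order(rh$gene_id, rh$go_id), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA = l, hallmark = h, path_count = nrow(rh),
        strong = nrow(rh) > strong_min,
        witnesses = paste(rh$gene_id, rh$go_id, sep = "|", collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(lncRNA = character(0), hallmark = character(0),
                      path_count = integer(0), strong = logical(0),
                      witnesses = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$path_count, out$lncRNA, out$hallmark), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hallmark degrees within a module
#'
#' Restricts the chart to one module's RNAs and counts, per hallmark, the
#' incident GO-layer edges (distinct GO-hallmark links reachable from the
#' module). Hallmarks with higher degree dominate the module's biology.
#'
#' @param chart a [build_chart()] result.
#' @param module_id module id present in the chart.
#' @return Named integer vector (hallmark -> count), descending; empty if
#'   the module reaches no hallmark.
#' @export
hallmark_degree <- function(chart, module_id) {
  stopifnot(inherits(chart, "tripartite_chart"))
  if (!module_id %in% chart$module)
    stopf("unknown module: %s", module_id)
  rnas <- names(chart$module)[chart$module == module_id]
  mg <- chart$mrna_go[chart$mrna_go$gene_id %in% rnas, , drop = FALSE]
  gh <- unique(chart$go_hallmark[chart$go_hallmark$go_id %in% mg$go_id, ,
                                 drop = FALSE])
  if (nrow(gh) == 0L) return(stats::setNames(integer(0), character(0)))
  cnt <- table(gh$hallmark)
  out <- stats::setNames(as.integer(cnt), names(cnt))
  out[order(-out, names(out))]
}

#' Export the hallmark association report and chart edge list
#'
#' @param chart a `tripartite_chart`.
#' @param associations a [predict_associations()] result.
#' @param assoc_path,chart_path output TSV paths (`NULL` to skip).
#' @param header_line optional `#` provenance line.
#' @return Invisibly, the paths written.
#' @export
write_hallmarks <- function(chart, associations, assoc_path = NULL,
                            chart_path = NULL, header_line = NULL) {
  written <- character(0)
  if (!is.null(assoc_path))
    written <- c(written, write_tsv(associations, assoc_path, header_line))
  if (!is.null(chart_path)) {
    edges <- rbind(
      data.frame(layer = "lncRNA-mRNA", from = chart$lnc_mrna$lncRNA,
                 to = chart$lnc_mrna$mRNA, stringsAsFactors = FALSE),
      data.frame(layer = "mRNA-GO", from = chart$mrna_go$gene_id,
                 to = chart$mrna_go$go_id, stringsAsFactors = FALSE),
      data.frame(layer = "GO-hallmark", from = chart$go_hallmark$go_id,
                 to = chart$go_hallmark$hallmark, stringsAsFactors = FALSE))
    written <- c(written, write_tsv(edges, chart_path, header_line))
  }
  invisible(written)
}
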