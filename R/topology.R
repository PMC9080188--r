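#' Node degrees of a network
#'
#' Number of edges incident to each node; the handshake identity
#' `sum(degree) == 2 * n_edges` always holds.
#'
#' @param net a `corr_network`.
#' @return Named integer vector.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  stats::setNames(net$nodes$degree, net$nodes$gene_id)
}

#' Betweenness centrality
#'
#' For node v, the sum over ordered pairs of other nodes of the fraction of
#' shortest paths between them that pass through v, halved for undirected
#' graphs (the usual convention). Computed with igraph's Brandes algorithm on
#' the unweighted graph.
#'
#' @param net a `corr_network`.
#' @param normalized divide by `(n-1)(n-2)/2`; default `FALSE` (raw values,
#'   as network-analysis tables usually report).
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  b[net$nodes$gene_id]
}

#' Topology table of a network
#'
#' Per-node degree, betweenness and module, with dense ranks by descending
#' degree and betweenness (the hub-ranking used to pick the most influential
#' RNAs).
#'
#' @param net a `corr_network`.
#' @param normalized passed to [betweenness_centrality()].
#' @return Data.frame: `gene_id`, `role`, `module`, `degree`, `betweenness`,
#'   `rank_by_degree`, `rank_by_betweenness`, ordered by descending degree.
#' @export
topology_table <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "corr_network"))
  btw <- betweenness_centrality(net, normalized = normalized)
  df <- data.frame(gene_id = net$nodes$gene_id,
                   role = net$nodes$role,
                   module = net$nodes$module,
                   degree = net$nodes$degree,
                   betweenness = unname(btw),
                   stringsAsFactors = FALSE)
  df$rank_by_degree <- match(-df$degree, sort(unique(-df$degree)))
  df$rank_by_betweenness <- match(-df$betweenness, sort(unique(-df$betweenness)))
  df <- df[order(-df$degree, -df$betweenness, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Log-log power-law fit of a degree distribution
#'
#' Least-squares line on (log k, log frequency(k)) over degrees with nonzero
#' frequency; the power-law exponent is minus the slope. Requires at least 3
#' distinct degree values.
#'
#' @param degrees integer vector of node degrees (>= 1).
#' @return List of class `power_law_fit`: `exponent`, `intercept`,
#'   `r_squared`, and the `k`/`frequency` profile used.
#' @export
fit_power_law <- function(degrees) {
  degrees <- as.integer(degrees)
  if (any(degrees < 1L)) stopf("degrees must be >= 1")
  tab <- table(degrees)
  if (length(tab) < 3L)
    stopf("need at least 3 distinct degree values (got %d)", length(tab))
  k <- as.integer(names(tab))
  freq <- as.integer(tab)
  fit <- stats::lm(log(freq) ~ log(k))
  structure(list(exponent = -unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 k = k, frequency = freq),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: frequency(k) ~ k^(-%.3f), R^2 = %.3f (%d distinct degrees)\n",
              x$exponent, x$r_squared, length(x$k)))
  invisible(x)
}

#' @export
plot.power_law_fit <- function(x, ...) {
  graphics::plot(x$k, x$frequency, log = "xy", pch = 19,
                 xlab = "degree k", ylab = "frequency",
                 main = sprintf("degree distribution (exponent %.2f)", x$exponent),
                 ...)
  kk <- range(x$k)
  graphics::lines(kk, exp(x$intercept) * kk^(-x$exponent), lty = 2)
  invisible(x)
}
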