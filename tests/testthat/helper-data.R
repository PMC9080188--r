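# Shared fixture builders (everything is generated in code at test time).

# A small expr_matrix built directly from a values matrix.
make_expr <- function(values, role = "mRNA", group = NULL, scale = "log2") {
  if (is.null(group))
    group <- rep(c("tumor", "normal"), length.out = ncol(values))
  expr_matrix(values, role = role, group = group, scale = scale)
}

# Random survival data without tied times.
rand_surv <- function(n, event_p = 0.7, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             time = round(stats::rexp(n, 1 / 500), 6) + 1e-6 * seq_len(n),
             event = stats::rbinom(n, 1, event_p),
             stringsAsFactors = FALSE)
}

# Random connected-ish undirected graph as a corr_network-shaped object.
make_net <- function(edges, roles) {
  ids <- sort(unique(c(edges$node_a, edges$node_b)))
  if (is.null(names(roles))) roles <- stats::setNames(rep_len(roles, length(ids)), ids)
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  ab <- cbind(pmin(edges$node_a, edges$node_b), pmax(edges$node_a, edges$node_b))
  edges <- data.frame(node_a = ab[, 1], node_b = ab[, 2],
                      r = if (is.null(edges$r)) 0.9 else edges$r,
                      p_value = if (is.null(edges$p_value)) 1e-6 else edges$p_value,
                      n = 100L, stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  deg <- table(factor(c(edges$node_a, edges$node_b), levels = ids))
  modules <- find_modules(edges)
  nodes <- data.frame(gene_id = ids, role = unname(roles[ids]),
                      degree = as.integer(deg[ids]),
                      module = unname(modules[ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, r_min = 0.85, p_max = 0.05,
                 use_abs = FALSE, sample_set = "all", n_samples = 100L),
            class = "corr_network")
}

rand_graph <- function(n_nodes, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n_nodes)]
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  data.frame(node_a = pairs[1, keep], node_b = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# Adjacency matrix of a corr_network (for the brute-force betweenness oracle).
net_adjacency <- function(net) {
  ids <- net$nodes$gene_id
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    adj[net$edges$node_a[i], net$edges$node_b[i]] <- TRUE
    adj[net$edges$node_b[i], net$edges$node_a[i]] <- TRUE
  }
  adj
}

# Small synthetic configs used across tests.
quick_config <- function(seed = 1, ...) {
  args <- list(n_tumor = 60, n_normal = 20, n_mrna = 30, n_lncrna = 10,
               n_modules = 2, module_size = c(8, 6), lncrna_per_module = c(2, 1),
               n_go_terms = 8, n_hallmarks = 3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# Config for signature-recovery experiments: 20 lncRNAs in 4 modules,
# 2 planted prognostic lncRNAs (module 1 and module 4) with beta = ln 2.
signature_config <- function(seed = 1, ...) {
  args <- list(n_tumor = 283, n_normal = 31, n_mrna = 20, n_lncrna = 20,
               n_modules = 4, module_size = c(10, 8, 6, 4),
               lncrna_per_module = c(8, 6, 4, 2),
               n_go_terms = 10, n_hallmarks = 5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# Tripartite chart input tables for a tiny fixed example:
# L1-M1 with M1 in 3 GO terms all mapping to hallmark H1.
tiny_chart_tables <- function() {
  net <- make_net(data.frame(node_a = "L1", node_b = "M1"),
                  roles = c(L1 = "lncRNA", M1 = "mRNA"))
  gene_go <- data.frame(gene_id = "M1", go_id = c("GO:1", "GO:2", "GO:3"),
                        stringsAsFactors = FALSE)
  go_hallmark <- data.frame(go_id = c("GO:1", "GO:2", "GO:3"),
                            hallmark = "H1", stringsAsFactors = FALSE)
  list(net = net, gene_go = gene_go, go_hallmark = go_hallmark)
}

# Random layered chart (<= 30 nodes) plus a matching corr_network.
rand_chart_tables <- function(seed) {
  set.seed(seed)
  n_l <- sample(2:4, 1); n_m <- sample(3:8, 1)
  n_g <- sample(3:8, 1); n_h <- sample(2:4, 1)
  lnc <- sprintf("L%02d", seq_len(n_l))
  mrna <- sprintf("M%02d", seq_len(n_m))
  gos <- sprintf("GO:%02d", seq_len(n_g))
  hms <- sprintf("H%d", seq_len(n_h))
  lm <- unique(data.frame(
    node_a = sample(lnc, 2 * n_m, replace = TRUE),
    node_b = sample(mrna, 2 * n_m, replace = TRUE),
    stringsAsFactors = FALSE))
  net <- make_net(lm, roles = stats::setNames(
    c(rep("lncRNA", n_l), rep("mRNA", n_m)), c(lnc, mrna)))
  gene_go <- unique(data.frame(
    gene_id = sample(mrna, 2 * n_g, replace = TRUE),
    go_id = sample(gos, 2 * n_g, replace = TRUE), stringsAsFactors = FALSE))
  go_hallmark <- unique(data.frame(
    go_id = sample(gos, 2 * n_g, replace = TRUE),
    hallmark = sample(hms, 2 * n_g, replace = TRUE), stringsAsFactors = FALSE))
  list(net = net, gene_go = gene_go, go_hallmark = go_hallmark)
}

# Write an expression TSV from a matrix of strings or numbers.
write_expr_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
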