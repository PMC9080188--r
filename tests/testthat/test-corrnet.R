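test_that("pearson_edge matches the longhand formula and cor.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  got <- pearson_edge(x, y)
  want <- brute_pearson(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    got <- pearson_edge(a, b)
    ct <- cor.test(a, b)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("pearson_edge handles identities and rejects bad input", {
  x <- c(1, 3, 2, 5)
  expect_equal(pearson_edge(x, x), list(r = 1, p_value = 0, n = 4))
  expect_equal(pearson_edge(x, -x)$r, -1)
  expect_error(pearson_edge(x, x[1:3]), "length")
  expect_error(pearson_edge(x[1:2], x[1:2]), "3")
  expect_error(pearson_edge(x, rep(1, 4)), "constant")
})

test_that("a single correlated pair yields a 2-node, 1-edge, 1-module network", {
  set.seed(5)
  base <- rnorm(50)
  v <- rbind(A = base, B = base + rnorm(50, sd = 0.05), C = rnorm(50))
  colnames(v) <- sprintf("S%02d", 1:50)
  x <- make_expr(v)
  net <- build_network(x, c("A", "B", "C"))
  expect_identical(net$nodes$gene_id, c("A", "B"))
  expect_identical(nrow(net$edges), 1L)
  expect_identical(unique(net$nodes$module), 1L)
  expect_gt(net$edges$r, 0.98)
})

test_that("build_network equals a brute-force pairwise recomputation", {
  x <- generate_expression(quick_config(seed = 13, planted_logfc = 0))
  cand <- genes(x)[1:20]
  net <- build_network(x, cand, r_min = 0.2, p_max = 0.05)
  brute <- list()
  for (i in 1:(length(cand) - 1)) for (j in (i + 1):length(cand)) {
    pe <- pearson_edge(x$values[cand[i], ], x$values[cand[j], ])
    if (pe$r > 0.2 && pe$p_value < 0.05) {
      a <- min(cand[i], cand[j]); b <- max(cand[i], cand[j])
      brute[[paste(a, b)]] <- c(a, b, pe$r)
    }
  }
  expect_identical(nrow(net$edges), length(brute))
  key <- paste(net$edges$node_a, net$edges$node_b)
  expect_setequal(key, names(brute))
  # r values agree pairwise
  for (k in seq_len(nrow(net$edges)))
    expect_equal(net$edges$r[k], as.numeric(brute[[key[k]]][3]), tolerance = 1e-12)
})

test_that("edges are invariant under row and column permutation", {
  x <- generate_expression(quick_config(seed = 21))
  cand <- genes(x)[1:15]
  net1 <- build_network(x, cand, r_min = 0.5)
  perm_s <- sample(samples(x))
  perm_g <- sample(genes(x))
  x2 <- expr_subset(x, genes = perm_g, samples = perm_s)
  net2 <- build_network(x2, sample(cand), r_min = 0.5)
  expect_equal(net1$edges[, c("node_a", "node_b")],
               net2$edges[, c("node_a", "node_b")])
})

test_that("the edge gate is strict at the threshold", {
  set.seed(9)
  x <- rnorm(40)
  z <- residuals(lm(rnorm(40) ~ x))
  xs <- (x - mean(x)) / sd(x); zs <- z / sd(z)
  y <- 0.85 * xs + sqrt(1 - 0.85^2) * zs
  r_exact <- cor(x, y)
  v <- rbind(A = x, B = y)
  colnames(v) <- sprintf("S%02d", 1:40)
  net <- build_network(make_expr(v), c("A", "B"), r_min = r_exact)
  expect_identical(nrow(net$edges), 0L)          # r > r_min strictly
  net2 <- build_network(make_expr(v), c("A", "B"), r_min = r_exact - 1e-9)
  expect_identical(nrow(net2$edges), 1L)
})

test_that("r_min = 1 on noisy data gives an empty network", {
  x <- generate_expression(quick_config(seed = 2))
  net <- build_network(x, genes(x)[1:10], r_min = 1)
  expect_identical(nrow(net$nodes), 0L)
  expect_identical(nrow(net$edges), 0L)
})

test_that("modules are the connected components with deterministic labels", {
  e <- data.frame(node_a = c("A", "B", "D"), node_b = c("B", "C", "E"))
  m <- find_modules(e)
  expect_identical(m[c("A", "B", "C")], c(A = 1L, B = 1L, C = 1L))
  expect_identical(m[c("D", "E")], c(D = 2L, E = 2L))
  full <- data.frame(node_a = c("A", "A", "A", "B", "B", "C"),
                     node_b = c("B", "C", "D", "C", "D", "D"))
  expect_identical(unique(unname(find_modules(full))), 1L)
  for (seed in 1:5) {
    g <- rand_graph(7, seed = seed)
    m <- find_modules(g)
    ids <- sort(unique(c(g$node_a, g$node_b)))
    expect_setequal(names(m), ids)          # union = node set, disjoint by construction
  }
})

test_that("planted module structure is recovered from synthetic data", {
  hits <- total <- 0
  for (seed in 1:3) {
    cfg <- synth_config(n_tumor = 283, n_normal = 31, n_mrna = 40, n_lncrna = 10,
                        n_modules = 2, module_size = c(15, 10),
                        lncrna_per_module = c(3, 2), planted_logfc = 0,
                        seed = seed)
    ds <- generate_dataset(cfg)
    truth <- ds$truth$module
    members <- names(truth)[truth > 0]
    net <- build_network(ds$expression, genes(ds$expression))
    found <- setNames(net$nodes$module, net$nodes$gene_id)
    for (m in unique(truth[members])) {
      tm <- names(truth)[truth == m]
      lab <- found[tm]
      maj <- as.integer(names(which.max(table(lab[!is.na(lab)]))))
      hits <- hits + sum(!is.na(lab) & lab == maj)
      total <- total + length(tm)
    }
  }
  expect_gt(hits / total, 0.95)
})

test_that("network tables export and re-read", {
  x <- generate_expression(quick_config(seed = 4))
  net <- build_network(x, genes(x), r_min = 0.5)
  ep <- tempfile(); np <- tempfile(); gp <- tempfile(fileext = ".graphml")
  write_network(net, ep, np, gp, header_line = "prov")
  e2 <- read.delim(ep, comment.char = "#")
  expect_identical(nrow(e2), nrow(net$edges))
  expect_true(file.exists(gp))
})
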