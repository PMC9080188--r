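test_that("a single route appears in the chart and counts correctly", {
  tc <- tiny_chart_tables()
  chart <- build_chart(tc$net, tc$gene_go, tc$go_hallmark)
  expect_identical(chart$lnc_mrna,
                   data.frame(lncRNA = "L1", mRNA = "M1", stringsAsFactors = FALSE))
  cnt <- count_paths(chart, "L1")
  expect_identical(cnt, c(H1 = 3L))     # 1 mRNA x 3 GO terms -> one hallmark
  expect_error(count_paths(chart, "L9"), "unknown")
})

test_that("RNAs without a hallmark route are dropped", {
  net <- make_net(data.frame(node_a = c("L1", "L2"), node_b = c("M1", "M2")),
                  roles = c(L1 = "lncRNA", L2 = "lncRNA",
                            M1 = "mRNA", M2 = "mRNA"))
  gene_go <- data.frame(gene_id = c("M1", "M2"), go_id = c("GO:1", "GO:2"))
  go_hallmark <- data.frame(go_id = "GO:1", hallmark = "H1")
  chart <- build_chart(net, gene_go, go_hallmark)
  # M2's GO term maps to no hallmark: M2 and its lncRNA L2 disappear
  expect_setequal(unique(chart$lnc_mrna$lncRNA), "L1")
  expect_false("M2" %in% chart$mrna_go$gene_id)
  expect_identical(chart$n_rna_dropped, 2L)
  # empty annotation: everything is dropped
  empty <- build_chart(net, gene_go[0, ], go_hallmark)
  expect_identical(nrow(empty$lnc_mrna), 0L)
  expect_error(build_chart(net, gene_go, go_hallmark[0, ]), "empty")
})

test_that("count_paths equals brute-force enumeration on random charts", {
  for (seed in 1:20) {
    tc <- rand_chart_tables(seed)
    chart <- build_chart(tc$net, tc$gene_go, tc$go_hallmark)
    for (l in unique(chart$lnc_mrna$lncRNA)) {
      got <- count_paths(chart, l)
      want <- brute_path_counts(chart$lnc_mrna, chart$mrna_go,
                                chart$go_hallmark, l)
      expect_identical(got, want)
    }
  }
})

test_that("chart construction is invariant to input row order", {
  tc <- rand_chart_tables(99)
  chart1 <- build_chart(tc$net, tc$gene_go, tc$go_hallmark)
  set.seed(1)
  chart2 <- build_chart(tc$net,
                        tc$gene_go[sample(nrow(tc$gene_go)), ],
                        tc$go_hallmark[sample(nrow(tc$go_hallmark)), ])
  expect_equal(chart1$lnc_mrna, chart2$lnc_mrna)
  expect_equal(chart1$mrna_go, chart2$mrna_go)
  expect_equal(chart1$go_hallmark, chart2$go_hallmark)
})

test_that("dropping an mRNA neighbor never increases a path count", {
  tc <- rand_chart_tables(7)
  chart <- build_chart(tc$net, tc$gene_go, tc$go_hallmark)
  lncs <- unique(chart$lnc_mrna$lncRNA)
  skip_if(length(lncs) == 0)
  l <- lncs[1]
  full <- count_paths(chart, l)
  drop_m <- chart$lnc_mrna$mRNA[chart$lnc_mrna$lncRNA == l][1]
  net2 <- tc$net
  keep <- !(net2$edges$node_a %in% drop_m | net2$edges$node_b %in% drop_m)
  net2$edges <- net2$edges[keep, , drop = FALSE]
  chart2 <- build_chart(net2, tc$gene_go, tc$go_hallmark)
  if (l %in% chart2$lnc_mrna$lncRNA) {
    reduced <- count_paths(chart2, l)
    for (h in names(reduced)) expect_lte(reduced[[h]], full[[h]])
  } else succeed()
})

test_that("the strong-association rule is strict at the threshold", {
  tc <- tiny_chart_tables()
  chart3 <- build_chart(tc$net, tc$gene_go, tc$go_hallmark)
  assoc3 <- predict_associations(chart3)          # path_count 3 > 2
  expect_identical(assoc3$path_count, 3L)
  expect_true(assoc3$strong)
  chart2 <- build_chart(tc$net, tc$gene_go[1:2, ], tc$go_hallmark)
  assoc2 <- predict_associations(chart2)          # path_count 2, not > 2
  expect_identical(assoc2$path_count, 2L)
  expect_false(assoc2$strong)
  expect_identical(nrow(predict_associations(build_chart(tc$net, tc$gene_go[0, ],
                                                         tc$go_hallmark))), 0L)
})

test_that("associations are local to modules", {
  # two disconnected L-M pairs = two modules
  net <- make_net(data.frame(node_a = c("L1", "L2"), node_b = c("M1", "M2")),
                  roles = c(L1 = "lncRNA", L2 = "lncRNA",
                            M1 = "mRNA", M2 = "mRNA"))
  gene_go <- data.frame(gene_id = c("M1", "M1", "M2"),
                        go_id = c("GO:1", "GO:2", "GO:3"))
  go_hallmark <- data.frame(go_id = c("GO:1", "GO:2", "GO:3"),
                            hallmark = c("H1", "H1", "H2"))
  chart <- build_chart(net, gene_go, go_hallmark)
  assoc <- predict_associations(chart)
  m1 <- net$nodes$module[net$nodes$gene_id == "L1"]
  sub_net <- net
  keep <- net$nodes$module == m1
  sub_net$nodes <- net$nodes[keep, , drop = FALSE]
  sub_net$edges <- net$edges[net$edges$node_a %in% sub_net$nodes$gene_id, , drop = FALSE]
  sub_assoc <- predict_associations(build_chart(sub_net, gene_go, go_hallmark))
  expect_equal(assoc[assoc$lncRNA == "L1", ], sub_assoc,
               ignore_attr = "row.names")
})

test_that("hallmark degree counts GO-layer edges per module", {
  net <- make_net(data.frame(node_a = "L1", node_b = c("M1", "M2")),
                  roles = c(L1 = "lncRNA", M1 = "mRNA", M2 = "mRNA"))
  gene_go <- data.frame(gene_id = c("M1", "M1", "M2", "M2", "M2"),
                        go_id = c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5"))
  go_hallmark <- data.frame(go_id = sprintf("GO:%d", 1:5),
                            hallmark = c("H1", "H1", "H1", "H1", "H2"))
  chart <- build_chart(net, gene_go, go_hallmark)
  hd <- hallmark_degree(chart, 1L)
  expect_identical(hd, c(H1 = 4L, H2 = 1L))
  # matrix-sum oracle: column sums of the GO x hallmark incidence table
  inc <- table(chart$go_hallmark$go_id, chart$go_hallmark$hallmark)
  expect_identical(unname(hd[colnames(inc)]), unname(as.integer(colSums(inc))))
  expect_error(hallmark_degree(chart, 99L), "unknown")
})
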