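test_that("generators are pure functions of config and seed", {
  cfg <- quick_config(seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$survival, b$survival)
  expect_identical(a$gene_go, b$gene_go)
  expect_identical(a$go_hallmark, b$go_hallmark)
  c <- generate_dataset(quick_config(seed = 8))
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("config invariants are enforced", {
  expect_error(quick_config(module_size = c(50, 50)), "modules request")
  expect_error(quick_config(noise_sd = 0), "noise_sd")
  expect_error(quick_config(within_module_correlation = 1), "correlation")
  expect_error(quick_config(censor_rate = 1), "censor_rate")
  expect_error(quick_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(quick_config(lncrna_per_module = c(9, 1)), "lncrna_per_module")
})

test_that("within-module correlation matches the factor-model target", {
  cfg <- synth_config(n_tumor = 283, n_normal = 31, n_mrna = 20, n_lncrna = 5,
                      n_modules = 1, module_size = 10, lncrna_per_module = 2,
                      within_module_correlation = 0.9, planted_logfc = 0,
                      seed = 11)
  x <- generate_expression(cfg)
  truth <- attr(x, "truth")
  members <- names(truth$module)[truth$module == 1]
  R <- cor(t(x$values[members, ]))
  mean_r <- mean(R[upper.tri(R)])
  expect_gt(mean_r, 0.85)
  expect_lt(mean_r, 0.95)
  # background genes stay uncorrelated with the module
  bg <- names(truth$module)[truth$module == 0][1:5]
  cross <- cor(t(x$values[members, ]), t(x$values[bg, ]))
  expect_lt(max(abs(cross)), 0.4)
})

test_that("planted fold changes land on the group mean difference", {
  cfg <- quick_config(seed = 3, planted_logfc = 3, noise_sd = 1)
  x <- generate_expression(cfg)
  truth <- attr(x, "truth")
  grp_diff <- rowMeans(x$values[, x$group == "tumor"]) -
    rowMeans(x$values[, x$group == "normal"])
  se <- cfg$noise_sd * sqrt(1 / cfg$n_tumor + 1 / cfg$n_normal)
  de <- truth$logfc != 0
  expect_true(all(abs(grp_diff[de] - truth$logfc[de]) < 4 * se))
  # null construction: no planted effect anywhere
  cfg0 <- quick_config(seed = 3, planted_logfc = 0)
  x0 <- generate_expression(cfg0)
  d0 <- rowMeans(x0$values[, x0$group == "tumor"]) -
    rowMeans(x0$values[, x0$group == "normal"])
  expect_true(all(abs(d0) < 4 * cfg0$noise_sd))
})

test_that("null survival times are exponential with the stated mean", {
  cfg <- quick_config(n_tumor = 283, seed = 5)
  x <- generate_expression(cfg)
  s <- generate_survival(x, beta = numeric(0), baseline_hazard = 1 / 500,
                         censor_rate = 0, seed = 9)
  expect_true(all(s$event == 1L))
  expect_true(all(s$time > 0))
  se <- 500 / sqrt(nrow(s))
  expect_lt(abs(mean(s$time) - 500), 3 * se)
})

test_that("a positive beta shortens survival of high expressors", {
  cfg <- quick_config(n_tumor = 200, seed = 6)
  x <- generate_expression(cfg)
  g <- "LNC0001"
  s <- generate_survival(x, beta = c(LNC0001 = 1), baseline_hazard = 1 / 500,
                         censor_rate = 0, seed = 10)
  ex <- x$values[g, s$sample_id]
  hi <- s$time[ex >= quantile(ex, 0.75)]
  lo <- s$time[ex <= quantile(ex, 0.25)]
  expect_lt(median(hi), median(lo))
})

test_that("censoring hits the requested rate and validates inputs", {
  cfg <- quick_config(n_tumor = 283, seed = 2)
  x <- generate_expression(cfg)
  s <- generate_survival(x, beta = c(LNC0001 = 0.5), baseline_hazard = 1 / 500,
                         censor_rate = 0.5, seed = 4)
  expect_lt(abs(mean(1 - s$event) - 0.5), 0.1)
  expect_error(generate_survival(x, numeric(0), 0, 0, 1), "baseline_hazard")
  expect_error(generate_survival(x, numeric(0), 1, 1.2, 1), "censor_rate")
  expect_error(generate_survival(x, c(NOPE = 1), 1, 0, 1), "NOPE")
})

test_that("synthetic annotation obeys its schema", {
  genes <- sprintf("G%d", 1:10)
  ann <- generate_annotation(genes, n_go = 5, n_hallmarks = 2,
                             paths_per_gene = 2, seed = 1)
  expect_true(all(ann$gene_go$gene_id %in% genes))
  expect_true(all(ann$gene_go$go_id %in% ann$go_hallmark$go_id))
  expect_true(all(ann$go_hallmark$hallmark %in% cancer_hallmarks[1:2]))
  # every GO term maps to at least one hallmark
  expect_setequal(unique(ann$go_hallmark$go_id), sprintf("GO:%07d", 1:5))
  ann2 <- generate_annotation(genes, 5, 2, 2, seed = 1)
  expect_identical(ann, ann2)
  empty <- generate_annotation(genes, 5, 2, paths_per_gene = 0, seed = 1)
  expect_identical(nrow(empty$gene_go), 0L)
  expect_error(generate_annotation(character(0), 5, 2), "empty gene list")
  expect_error(generate_annotation(genes, 2, 5), "n_go")
})
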