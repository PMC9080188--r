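# a hand-built cox_fit stub: build_signature only reads coefficients,
# hazard_ratio and p_value from the fit
stub_fit <- function(beta, p) {
  structure(list(coefficients = beta, hazard_ratio = exp(beta),
                 p_value = p, se = abs(beta) / 2,
                 z = beta, var = diag(length(beta)),
                 loglik = c(null = 0, final = 0), iter = 1L,
                 converged = TRUE, n = 0L, n_event = 0L),
            class = "cox_fit")
}

test_that("risk scores follow the stated linear formula", {
  v <- rbind(g1 = c(2, 0, 1, 4), g2 = c(1, 0, 2, 1))
  colnames(v) <- sprintf("P%d", 1:4)
  x <- make_expr(v, role = "lncRNA", group = "tumor")
  s <- data.frame(sample_id = colnames(v), time = c(100, 200, 300, 400),
                  event = c(1, 1, 0, 1))
  fit <- stub_fit(c(g1 = 0.5, g2 = -1.0), c(g1 = 0.01, g2 = 0.02))
  sig <- build_signature(x, s, fit = fit, split = "median", minprop = 0.25)
  expect_equal(unname(sig$scores["P1"]), 2 * 0.5 + 1 * (-1.0))  # = 0
  expect_equal(unname(sig$scores), as.numeric(crossprod(v, c(0.5, -1))))
  expect_identical(sig$members$gene_id, c("g1", "g2"))
})

test_that("membership is strict at p_max and failure is informative", {
  v <- matrix(rnorm(20), 2, dimnames = list(c("g1", "g2"), sprintf("P%d", 1:10)))
  x <- make_expr(v, role = "lncRNA", group = "tumor")
  s <- rand_surv(10, seed = 2); s$sample_id <- colnames(v)
  fit <- stub_fit(c(g1 = 1, g2 = 1), c(g1 = 0.05, g2 = 0.3))
  expect_error(build_signature(x, s, fit = fit), "0.05")     # 0.05 is NOT < 0.05
  fit2 <- stub_fit(c(g1 = 1, g2 = 1), c(g1 = 0.049, g2 = 0.3))
  sig <- build_signature(x, s, fit = fit2, split = "median")
  expect_identical(sig$members$gene_id, "g1")
})

test_that("risk score contribution scales linearly with expression", {
  ds <- generate_dataset(quick_config(n_tumor = 80, seed = 14))
  x <- ds$expression
  fit <- stub_fit(c(LNC0001 = 0.4, LNC0002 = -0.2),
                  c(LNC0001 = 0.01, LNC0002 = 0.01))
  sig <- build_signature(x, ds$survival, fit = fit, split = "median")
  x2 <- x
  x2$values["LNC0001", ] <- 3 * x2$values["LNC0001", ]
  sig2 <- build_signature(x2, ds$survival, fit = fit, split = "median")
  delta <- sig2$scores - sig$scores
  expect_equal(unname(delta),
               unname(2 * x$values["LNC0001", ds$survival$sample_id] * 0.4),
               tolerance = 1e-12)
})

test_that("risk grouping is a monotone function of the score", {
  ds <- generate_dataset(quick_config(n_tumor = 100, seed = 15))
  sig <- build_signature(ds$expression, ds$survival,
                         fit = stub_fit(c(LNC0001 = 1), c(LNC0001 = 0.001)))
  expect_identical(unname(sig$risk_group == "High-risk"),
                   unname(sig$scores > sig$cutpoint))
  # any strictly monotone transform of scores and cutpoint preserves groups
  expect_identical(unname(sig$risk_group == "High-risk"),
                   unname(exp(sig$scores) > exp(sig$cutpoint)))
})

test_that("a planted prognostic lncRNA is recovered as a member", {
  for (seed in 1:3) {
    cfg <- quick_config(n_tumor = 283, seed = 20 + seed,
                        survival_beta = c(LNC0009 = log(2)))  # background lncRNA
    ds <- generate_dataset(cfg)
    sig <- build_signature(ds$expression, ds$survival,
                           genes = sprintf("LNC%04d", 6:10))
    expect_true("LNC0009" %in% sig$members$gene_id)
  }
})

test_that("evaluation reports mortality, log-rank and ROC coherently", {
  cfg <- signature_config(seed = 5)
  ds <- generate_dataset(cfg)
  sig <- build_signature(ds$expression, ds$survival)
  ev <- evaluate_signature(sig, ds$survival)
  expect_gt(ev$mortality_rate[["High-risk"]], ev$mortality_rate[["Low-risk"]])
  expect_lt(ev$logrank$p_value, 0.05)
  expect_gt(ev$roc$auc, 0.5)
  expect_equal(sum(ev$n), nrow(ds$survival))
  expect_equal(unname(ev$mortality_rate[["High-risk"]]),
               mean(ds$survival$event[sig$risk_group[ds$survival$sample_id] == "High-risk"]))
})

test_that("identical survival in both groups gives p = 1 and equal mortality", {
  v <- matrix(rnorm(16), 2, dimnames = list(c("g1", "g2"), sprintf("P%d", 1:8)))
  x <- make_expr(v, role = "lncRNA", group = "tumor")
  tvec <- rep(c(50, 120, 300, 500), 2)
  evec <- rep(c(1, 0, 1, 1), 2)
  s <- data.frame(sample_id = colnames(v), time = tvec, event = evec)
  sig <- structure(list(members = data.frame(gene_id = "g1", beta = 1,
                                             hazard_ratio = exp(1), p_value = 0.01),
                        scores = setNames(rnorm(8), colnames(v)),
                        cutpoint = 0, split = "median",
                        risk_group = setNames(factor(rep(c("Low-risk", "High-risk"), each = 4),
                                                     levels = c("Low-risk", "High-risk")),
                                              colnames(v)),
                        fit = NULL), class = "risk_signature")
  ev <- evaluate_signature(sig, s, horizon = 200)
  expect_equal(unname(ev$mortality_rate[["Low-risk"]]),
               unname(ev$mortality_rate[["High-risk"]]))
  expect_equal(ev$logrank$p_value, 1)
})

test_that("signature tables export", {
  ds <- generate_dataset(signature_config(seed = 6))
  sig <- build_signature(ds$expression, ds$survival)
  ev <- evaluate_signature(sig, ds$survival)
  mp <- tempfile(); sp <- tempfile(); rp <- tempfile()
  write_signature(sig, ev, mp, sp, rp, header_line = "prov")
  sc <- read.delim(sp, comment.char = "#")
  expect_identical(nrow(sc), nrow(ds$survival))
  expect_true(all(c("risk_score", "risk_group") %in% colnames(sc)))
})
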