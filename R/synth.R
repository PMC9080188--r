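# Synthetic data generator emulating a two-group (tumor/normal) bulk
# transcriptome study with block-correlated gene modules, planted fold
# changes, proportional-hazards survival linked to designated lncRNAs, and a
# toy GO/hallmark annotation. All generators are pure functions of their
# configuration and seed.

#' The ten canonical cancer hallmarks
#'
#' Used as the hallmark vocabulary of the synthetic GO-to-hallmark mapping.
#' @export
cancer_hallmarks <- c(
  "Sustaining proliferative signaling",
  "Evading growth suppressors",
  "Resisting cell death",
  "Enabling replicative immortality",
  "Inducing angiogenesis",
  "Activating invasion and metastasis",
  "Deregulating cellular energetics",
  "Avoiding immune destruction",
  "Genome instability and mutation",
  "Tumor-promoting inflammation")

#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror the study design the analysis pipeline assumes: 283 tumor
#' and 31 normal samples; 424 mRNA and 42 lncRNA differential-expression
#' candidates; four correlated modules totalling 108 genes (88 mRNA + 20
#' lncRNA) with within-module Pearson correlation 0.9; planted |log2 fold
#' change| of 3 (sign alternating by module); exponential survival for tumor
#' samples driven by two prognostic lncRNAs with log-hazard ratio ln 2, one in
#' the largest and one in the smallest module; ~55% independent censoring.
#'
#' @param n_tumor,n_normal sample counts per group.
#' @param n_mrna,n_lncrna gene counts per RNA class.
#' @param n_modules number of correlated modules.
#' @param module_size genes per module; scalar or length-`n_modules` vector.
#' @param lncrna_per_module lncRNAs allocated to each module; scalar or
#'   length-`n_modules` vector; remainder of each module is mRNA.
#' @param within_module_correlation target pairwise Pearson correlation of
#'   module members, in (0, 1).
#' @param planted_logfc absolute tumor-minus-normal mean difference (log2
#'   units) given to planted DE genes.
#' @param background_de_fraction fraction of non-module genes that are also
#'   planted DE (sign alternating); 1 means every gene is a DE candidate.
#' @param noise_sd total per-gene standard deviation on the log2 scale.
#' @param survival_beta named numeric vector mapping prognostic lncRNA ids to
#'   their log hazard ratio per expression unit; `NULL` picks the first
#'   lncRNA of module 1 and of the last module, both at `log(2)`.
#' @param baseline_hazard exponential baseline hazard (events/day).
#' @param censor_rate target fraction of censored tumor samples, in [0, 1).
#' @param n_go_terms,n_hallmarks,paths_per_gene size of the synthetic
#'   annotation: GO vocabulary, hallmark vocabulary (at most 10, drawn from
#'   [cancer_hallmarks]), and GO terms drawn per mRNA.
#' @param seed integer; fully determines all generated data.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_tumor = 283, n_normal = 31,
                         n_mrna = 424, n_lncrna = 42,
                         n_modules = 4,
                         module_size = c(40, 30, 22, 16),
                         lncrna_per_module = c(8, 6, 4, 2),
                         within_module_correlation = 0.9,
                         planted_logfc = 3,
                         background_de_fraction = 1,
                         noise_sd = 1,
                         survival_beta = NULL,
                         baseline_hazard = 1 / 1000,
                         censor_rate = 0.55,
                         n_go_terms = 30, n_hallmarks = 10,
                         paths_per_gene = 2,
                         seed = 1L) {
  for (nm in c("n_tumor", "n_normal", "n_mrna", "n_lncrna", "n_modules",
               "n_go_terms", "n_hallmarks"))
    if (!is_count(get(nm))) stopf("`%s` must be a positive integer", nm)
  module_size <- as.integer(rep_len(module_size, n_modules))
  lncrna_per_module <- as.integer(rep_len(lncrna_per_module, n_modules))
  if (any(module_size < 1L)) stopf("module sizes must be >= 1")
  if (any(lncrna_per_module < 0L) || any(lncrna_per_module > module_size))
    stopf("lncrna_per_module must be between 0 and module_size")
  if (sum(module_size) > n_mrna + n_lncrna)
    stopf("modules request %d genes but only %d exist",
          sum(module_size), n_mrna + n_lncrna)
  if (sum(lncrna_per_module) > n_lncrna)
    stopf("modules request %d lncRNAs but only %d exist",
          sum(lncrna_per_module), n_lncrna)
  if (sum(module_size - lncrna_per_module) > n_mrna)
    stopf("modules request more mRNAs than exist")
  rho <- within_module_correlation
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stopf("within_module_correlation must lie in (0, 1)")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("noise_sd must be > 0")
  if (!is.numeric(planted_logfc) || length(planted_logfc) != 1L)
    stopf("planted_logfc must be a single number")
  if (!is.numeric(background_de_fraction) || background_de_fraction < 0 ||
      background_de_fraction > 1)
    stopf("background_de_fraction must lie in [0, 1]")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stopf("baseline_hazard must be > 0")
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    stopf("censor_rate must lie in [0, 1)")
  if (n_hallmarks > length(cancer_hallmarks))
    stopf("at most %d hallmarks available", length(cancer_hallmarks))
  if (n_go_terms < n_hallmarks) stopf("need n_go_terms >= n_hallmarks")
  if (!is_count(paths_per_gene, min = 0L)) stopf("paths_per_gene must be >= 0")
  if (!is_count(seed, min = 0L) || seed > 2^31 - 10)
    stopf("seed must be a non-negative integer below 2^31 - 10")

  lnc_ids <- sprintf("LNC%04d", seq_len(n_lncrna))
  if (is.null(survival_beta)) {
    first_of_last <- sum(lncrna_per_module[-n_modules]) + 1L
    survival_beta <- stats::setNames(c(log(2), log(2)),
                                     lnc_ids[c(1L, first_of_last)])
  }
  if (length(survival_beta) && is.null(names(survival_beta)))
    stopf("survival_beta must be a named vector (lncRNA id -> beta)")

  structure(list(
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
    n_modules = as.integer(n_modules), module_size = module_size,
    lncrna_per_module = lncrna_per_module,
    within_module_correlation = rho,
    planted_logfc = planted_logfc,
    background_de_fraction = background_de_fraction,
    noise_sd = noise_sd,
    survival_beta = survival_beta,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    n_go_terms = as.integer(n_go_terms),
    n_hallmarks = as.integer(n_hallmarks),
    paths_per_gene = as.integer(paths_per_gene),
    seed = as.integer(seed)), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("synth_config: %d tumor + %d normal samples, %d mRNA + %d lncRNA\n",
              x$n_tumor, x$n_normal, x$n_mrna, x$n_lncrna))
  cat(sprintf("  %d modules (sizes %s; lncRNA %s), rho = %.2f, |logFC| = %g\n",
              x$n_modules, paste(x$module_size, collapse = "/"),
              paste(x$lncrna_per_module, collapse = "/"),
              x$within_module_correlation, x$planted_logfc))
  cat(sprintf("  prognostic lncRNAs: %s (beta %s); h0 = %g/day, censor %.0f%%; seed %d\n",
              paste(names(x$survival_beta), collapse = ", "),
              paste(signif(x$survival_beta, 3), collapse = ", "),
              x$baseline_hazard, 100 * x$censor_rate, x$seed))
  invisible(x)
}

# Module id (0 = background) per gene, lncRNAs first within each module.
synth_gene_layout <- function(config) {
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
  mrna_ids <- sprintf("MRNA%04d", seq_len(config$n_mrna))
  lnc_mod <- rep(0L, config$n_lncrna)
  mrna_mod <- rep(0L, config$n_mrna)
  li <- 0L; mi <- 0L
  for (m in seq_len(config$n_modules)) {
    nl <- config$lncrna_per_module[m]
    nm <- config$module_size[m] - nl
    if (nl > 0L) lnc_mod[li + seq_len(nl)] <- m
    if (nm > 0L) mrna_mod[mi + seq_len(nm)] <- m
    li <- li + nl; mi <- mi + nm
  }
  list(gene_id = c(mrna_ids, lnc_ids),
       role = c(rep("mRNA", config$n_mrna), rep("lncRNA", config$n_lncrna)),
       module = stats::setNames(c(mrna_mod, lnc_mod), c(mrna_ids, lnc_ids)))
}

#' Generate a synthetic log2 expression matrix
#'
#' Gaussian latent-factor model on the log2 scale: members of module m share a
#' per-sample factor so that each within-module pair has correlation
#' `within_module_correlation`; planted DE genes get a tumor-minus-normal mean
#' shift of `planted_logfc` (sign alternating by module, and for background DE
#' genes by index); all other genes have equal group means. Deterministic
#' given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return An [expr_matrix] (scale `"log2"`) with a `truth` attribute: list
#'   with `module` (named module id per gene, 0 = background), `logfc`
#'   (named planted shift per gene) and `de_genes`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lay <- synth_gene_layout(config)
  G <- length(lay$gene_id)
  sid <- c(sprintf("N%03d", seq_len(config$n_normal)),
           sprintf("T%03d", seq_len(config$n_tumor)))
  grp <- c(rep("normal", config$n_normal), rep("tumor", config$n_tumor))
  S <- length(sid)
  rho <- config$within_module_correlation
  sdv <- config$noise_sd

  with_seed(config$seed, {
    mu <- stats::rnorm(G, mean = 6, sd = 1.5)
    lfc <- numeric(G)
    inmod <- lay$module > 0L
    lfc[inmod] <- config$planted_logfc *
      ifelse(lay$module[inmod] %% 2L == 1L, 1, -1)
    bg <- which(!inmod)
    if (length(bg) && config$background_de_fraction > 0) {
      n_de_bg <- round(config$background_de_fraction * length(bg))
      if (n_de_bg > 0) {
        de_bg <- bg[sample.int(length(bg), n_de_bg)]
        lfc[de_bg] <- config$planted_logfc *
          rep_len(c(1, -1), length(de_bg))
      }
    }
    fac <- matrix(stats::rnorm(config$n_modules * S), config$n_modules, S)
    eps <- matrix(stats::rnorm(G * S), G, S)
    vals <- matrix(mu, G, S) + outer(lfc, as.numeric(grp == "tumor"))
    vals <- vals + sdv * sqrt(1 - ifelse(inmod, rho, 0)) * eps
    if (any(inmod))
      vals[inmod, ] <- vals[inmod, , drop = FALSE] +
        sdv * sqrt(rho) * fac[lay$module[inmod], , drop = FALSE]
    dimnames(vals) <- list(lay$gene_id, sid)
    x <- expr_matrix(vals, role = lay$role, group = grp, scale = "log2")
    attr(x, "truth") <- list(
      module = lay$module,
      logfc = stats::setNames(lfc, lay$gene_id),
      de_genes = lay$gene_id[lfc != 0])
    x
  })
}

#' Generate survival outcomes under a proportional-hazards model
#'
#' Event times for the tumor samples are drawn from an exponential
#' proportional-hazards model: hazard
#' `baseline_hazard * exp(sum_g beta_g * centered expression of g)`.
#' Censoring is independent exponential with a rate solved numerically so the
#' expected censored fraction equals `censor_rate`.
#'
#' @param x an [expr_matrix] containing the genes named in `beta`.
#' @param beta named numeric vector, lncRNA id -> log hazard ratio. May be
#'   empty (no expression effect).
#' @param baseline_hazard positive baseline hazard (events/day).
#' @param censor_rate target censored fraction in [0, 1); 0 means every
#'   subject's death is observed.
#' @param seed integer seed.
#' @return Data.frame with columns `sample_id`, `time` (days, > 0) and
#'   `event` (1 = death observed, 0 = censored), one row per tumor sample.
#' @export
generate_survival <- function(x, beta, baseline_hazard, censor_rate, seed) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stopf("baseline_hazard must be > 0")
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    stopf("censor_rate must lie in [0, 1)")
  missing <- setdiff(names(beta), rownames(x$values))
  if (length(missing)) stopf("beta names not in expression matrix: %s",
                             paste(missing, collapse = ", "))
  tum <- names(x$group)[x$group == "tumor"]
  if (length(tum) < 2L) stopf("need at least 2 tumor samples")
  eta <- rep(0, length(tum))
  if (length(beta)) {
    ex <- x$values[names(beta), tum, drop = FALSE]
    ex <- ex - rowMeans(ex)
    eta <- as.numeric(crossprod(ex, beta))
  }
  lambda <- baseline_hazard * exp(eta)
  with_seed(seed, {
    t_event <- stats::rexp(length(tum), rate = lambda)
    if (censor_rate > 0) {
      # P(C < T_i) = c / (c + lambda_i); solve mean over i = censor_rate
      f <- function(cr) mean(cr / (cr + lambda)) - censor_rate
      cr <- stats::uniroot(f, lower = 1e-12,
                           upper = max(lambda) * 1e6)$root
      t_cens <- stats::rexp(length(tum), rate = cr)
      data.frame(sample_id = tum,
                 time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = tum, time = t_event, event = 1L,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Generate a synthetic gene-to-GO and GO-to-hallmark annotation
#'
#' Each gene draws `paths_per_gene` GO terms (duplicates collapsed); every GO
#' term maps to one or two cancer hallmarks, so each GO id appears in at least
#' one `go_hallmark` row. Deterministic given `seed`.
#'
#' @param genes character vector of gene ids to annotate (typically the mRNAs).
#' @param n_go,n_hallmarks vocabulary sizes, `n_go >= n_hallmarks >= 1`.
#' @param paths_per_gene GO terms drawn per gene (0 gives an empty gene table).
#' @param seed integer seed.
#' @return List with data.frames `gene_go` (`gene_id`, `go_id`) and
#'   `go_hallmark` (`go_id`, `hallmark`).
#' @export
generate_annotation <- function(genes, n_go, n_hallmarks, paths_per_gene = 2,
                                seed = 1L) {
  if (length(genes) == 0L) stopf("empty gene list")
  if (!is_count(n_go) || !is_count(n_hallmarks) || n_go < n_hallmarks)
    stopf("need n_go >= n_hallmarks >= 1")
  if (n_hallmarks > length(cancer_hallmarks))
    stopf("at most %d hallmarks available", length(cancer_hallmarks))
  if (!is_count(paths_per_gene, min = 0L)) stopf("paths_per_gene must be >= 0")
  go_ids <- sprintf("GO:%07d", seq_len(n_go))
  hm <- cancer_hallmarks[seq_len(n_hallmarks)]
  with_seed(seed, {
    if (paths_per_gene > 0L) {
      gene_go <- do.call(rbind, lapply(genes, function(g) {
        terms <- unique(sample(go_ids, paths_per_gene, replace = TRUE))
        data.frame(gene_id = g, go_id = sort(terms), stringsAsFactors = FALSE)
      }))
    } else {
      gene_go <- data.frame(gene_id = character(), go_id = character(),
                            stringsAsFactors = FALSE)
    }
    go_hallmark <- do.call(rbind, lapply(go_ids, function(go) {
      k <- sample(1:2, 1L)
      data.frame(go_id = go, hallmark = sort(sample(hm, min(k, length(hm)))),
                 stringsAsFactors = FALSE)
    }))
    list(gene_go = gene_go, go_hallmark = go_hallmark)
  })
}

#' Generate a complete synthetic dataset
#'
#' Bundles [generate_expression()], [generate_survival()] (tumor samples only;
#' seeded with `seed + 1`) and [generate_annotation()] over the mRNAs (seeded
#' with `seed + 2`), together with the ground truth used by recovery tests.
#'
#' @param config a [synth_config()].
#' @return List of class `synthetic_dataset`: `expression`, `survival`,
#'   `gene_go`, `go_hallmark`, `truth` (planted modules, logFCs, DE genes and
#'   prognostic lncRNA betas) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  x <- generate_expression(config)
  truth <- attr(x, "truth")
  truth$prognostic <- config$survival_beta
  surv <- generate_survival(x, config$survival_beta, config$baseline_hazard,
                            config$censor_rate, seed = config$seed + 1L)
  ann <- generate_annotation(rownames(x$values)[x$role == "mRNA"],
                             n_go = config$n_go_terms,
                             n_hallmarks = config$n_hallmarks,
                             paths_per_gene = config$paths_per_gene,
                             seed = config$seed + 2L)
  structure(list(expression = x, survival = surv,
                 gene_go = ann$gene_go, go_hallmark = ann$go_hallmark,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset\n")
  print(x$expression)
  cat(sprintf("  survival: %d tumor samples, %d events (%.0f%% censored)\n",
              nrow(x$survival), sum(x$survival$event),
              100 * mean(1 - x$survival$event)))
  cat(sprintf("  annotation: %d gene-GO rows, %d GO-hallmark rows\n",
              nrow(x$gene_go), nrow(x$go_hallmark)))
  cat(sprintf("  truth: %d DE genes, %d module genes, prognostic: %s\n",
              length(x$truth$de_genes), sum(x$truth$module > 0),
              paste(names(x$truth$prognostic), collapse = ", ")))
  invisible(x)
}
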