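#' Pipeline configuration
#'
#' Collects every stage threshold plus either a synthetic-data configuration
#' or input file paths. Thresholds default to the canonical gates:
#' DE `fdr < 0.05`, `|logFC| > 2`; edges `r > 0.85`, `p < 0.05`; screening,
#' Cox membership and log-rank significance at `p < 0.05`; cutpoint
#' `minprop = 0.1`; hallmark `strong` rule path count `> 2`.
#'
#' @param synth a [synth_config()] (synthetic mode), or `NULL` when file
#'   inputs are given.
#' @param mrna_path,lncrna_path,annotation_path,gene_go_path,go_hallmark_path
#'   input TSV paths (file mode; raw-scale expression, preprocessed by the
#'   pipeline).
#' @param fdr_max,lfc_min DE candidate gate.
#' @param gate_on gate DE candidates on `"fdr"` (default) or raw `"p"`.
#' @param r_min,edge_p_max network edge gate.
#' @param sample_set sample columns used for correlations (`"all"`,
#'   `"tumor"`, `"normal"`).
#' @param screen_p_max per-lncRNA screening significance level.
#' @param cox_p_max signature membership threshold.
#' @param minprop cutpoint scan minimum group proportion.
#' @param split risk-group split rule, `"cutpoint"` or `"median"`.
#' @param strong_min hallmark association strength threshold (strict >).
#' @param roc_horizon ROC horizon in days (`NULL`: median observed time).
#' @param pseudocount log2 pseudocount for preprocessing file inputs.
#' @param seed integer seed (used in synthetic mode).
#' @param outdir output directory for stage TSVs (`NULL`: no files written).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            mrna_path = NULL, lncrna_path = NULL,
                            annotation_path = NULL, gene_go_path = NULL,
                            go_hallmark_path = NULL,
                            fdr_max = 0.05, lfc_min = 2,
                            gate_on = c("fdr", "p"),
                            r_min = 0.85, edge_p_max = 0.05,
                            sample_set = c("all", "tumor", "normal"),
                            screen_p_max = 0.05, cox_p_max = 0.05,
                            minprop = 0.1, split = c("cutpoint", "median"),
                            strong_min = 2, roc_horizon = NULL,
                            pseudocount = 1,
                            seed = NULL, outdir = NULL) {
  gate_on <- match.arg(gate_on)
  sample_set <- match.arg(sample_set)
  split <- match.arg(split)
  file_mode <- !is.null(mrna_path)
  if (!file_mode && is.null(synth))
    stopf("either a synth config or input file paths are required")
  if (file_mode && (is.null(lncrna_path) || is.null(annotation_path) ||
                    is.null(gene_go_path) || is.null(go_hallmark_path)))
    stopf("file mode needs mrna, lncrna, annotation, gene_go and go_hallmark paths")
  for (nm in c("fdr_max", "edge_p_max", "screen_p_max", "cox_p_max")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v > 1) stopf("`%s` must lie in (0, 1]", nm)
  }
  if (!is.numeric(lfc_min) || lfc_min < 0) stopf("`lfc_min` must be >= 0")
  if (!is.numeric(r_min) || r_min <= -1 || r_min > 1) stopf("`r_min` must lie in (-1, 1]")
  if (!is.numeric(minprop) || minprop <= 0 || minprop > 0.5)
    stopf("`minprop` must lie in (0, 0.5]")
  if (!is_count(strong_min, min = 0L)) stopf("`strong_min` must be >= 0")
  if (is.null(seed)) seed <- if (!is.null(synth)) synth$seed else 1L
  structure(list(synth = synth, mrna_path = mrna_path,
                 lncrna_path = lncrna_path, annotation_path = annotation_path,
                 gene_go_path = gene_go_path, go_hallmark_path = go_hallmark_path,
                 fdr_max = fdr_max, lfc_min = lfc_min, gate_on = gate_on,
                 r_min = r_min, edge_p_max = edge_p_max, sample_set = sample_set,
                 screen_p_max = screen_p_max, cox_p_max = cox_p_max,
                 minprop = minprop, split = split, strong_min = strong_min,
                 roc_horizon = roc_horizon, pseudocount = pseudocount,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

pipeline_error <- function(stage, e, completed) {
  stopf("stage '%s' failed: %s [completed stages: %s]", stage,
        conditionMessage(e),
        if (length(completed)) paste(completed, collapse = ", ") else "none")
}

#' Run the full lncRNA network-and-signature pipeline
#'
#' Executes the stages in order: data (generate or load + preprocess),
#' differential expression, candidate selection, co-expression network,
#' topology, per-lncRNA survival screening, multivariate Cox signature with
#' evaluation, and hallmark association. Each stage consumes the previous
#' stage's output; any stage error aborts with the stage name and the list of
#' completed stages. If no lncRNA reaches the Cox membership threshold the
#' signature and evaluation slots are `NULL` and the run continues (a
#' screening pipeline should report "nothing significant", not die).
#'
#' With `config$outdir` set, every stage writes its table as TSV (first line
#' a `#` comment carrying the config hash and seed); reruns with the same
#' config and seed produce byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `lnc_pipeline` bundling `dataset`, `de`,
#'   `candidates`, `network`, `topology`, `power_law`, `screening`, `fit`,
#'   `signature`, `evaluation`, `chart`, `associations`, the run `log`
#'   (character vector) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(unclass(config)[setdiff(names(config), "outdir")])
  header <- sprintf("lncnetsig config=%s seed=%d", hash, config$seed)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  log <- character(0)
  completed <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  out_path <- function(name) if (is.null(outdir)) NULL else file.path(outdir, name)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) pipeline_error(name, e, completed))
    completed <<- c(completed, name)
    res
  }

  dataset <- stage("data", {
    if (!is.null(config$mrna_path)) {
      mrna <- read_expression(config$mrna_path, role = "mRNA")
      lncrna <- read_expression(config$lncrna_path, role = "lncRNA")
      annot <- read_annotation(config$annotation_path)
      merged <- merge_profiles(mrna, lncrna, annot)
      merged <- preprocess(merged, pseudocount = config$pseudocount)
      sv <- annot[annot$group == "tumor" & !is.na(annot$os_time) &
                    annot$os_time > 0, , drop = FALSE]
      sv <- sv[sv$sample_id %in% colnames(merged$values), , drop = FALSE]
      surv <- data.frame(sample_id = sv$sample_id, time = sv$os_time,
                         event = sv$os_event, stringsAsFactors = FALSE)
      gg <- read_tsv(config$gene_go_path)
      gh <- read_tsv(config$go_hallmark_path)
      note("stage=data mode=files genes=%d samples=%d surv=%d",
           nrow(merged$values), ncol(merged$values), nrow(surv))
      list(expression = merged, survival = surv, gene_go = gg,
           go_hallmark = gh, truth = NULL)
    } else {
      ds <- generate_dataset(config$synth)
      note("stage=data mode=synthetic genes=%d samples=%d surv=%d seed=%d",
           nrow(ds$expression$values), ncol(ds$expression$values),
           nrow(ds$survival), config$seed)
      ds
    }
  })
  expr <- dataset$expression
  surv <- as_survival_table(dataset$survival)

  de <- stage("de", {
    d <- differential_expression(expr, fdr_max = config$fdr_max,
                                 lfc_min = config$lfc_min,
                                 gate_on = config$gate_on)
    note("stage=de genes=%d gate_pass=%d (gate %s<%g, |logFC|>%g)",
         nrow(d), sum(d$passes_gate), config$gate_on, config$fdr_max,
         config$lfc_min)
    if (!is.null(outdir)) write_de_table(d, out_path("de_table.tsv"), header)
    d
  })

  candidates <- stage("candidates", {
    cand <- select_candidates(de, fdr_max = config$fdr_max,
                              lfc_min = config$lfc_min)
    if (config$gate_on == "p")
      cand <- de$gene_id[de$passes_gate]
    if (length(cand) < 2L) stopf("fewer than 2 candidate RNAs pass the DE gate")
    note("stage=candidates n=%d", length(cand))
    cand
  })

  network <- stage("network", {
    net <- build_network(expr, candidates, r_min = config$r_min,
                         p_max = config$edge_p_max,
                         sample_set = config$sample_set)
    if (nrow(net$nodes) == 0L) stopf("empty network: no RNA pair passes r > %g",
                                     config$r_min)
    note("stage=network nodes=%d edges=%d modules=%d",
         nrow(net$nodes), nrow(net$edges),
         max(net$nodes$module))
    if (!is.null(outdir))
      write_network(net, out_path("network_edges.tsv"),
                    out_path("network_nodes.tsv"), header_line = header)
    net
  })

  topo <- stage("topology", {
    tt <- topology_table(network)
    pl <- if (length(unique(tt$degree)) >= 3L) fit_power_law(tt$degree) else NULL
    note("stage=topology max_degree=%d powerlaw=%s", max(tt$degree),
         if (is.null(pl)) "degenerate" else sprintf("%.3f", pl$exponent))
    if (!is.null(outdir)) write_tsv(tt, out_path("topology.tsv"), header)
    list(table = tt, power_law = pl)
  })

  net_lncs <- network$nodes$gene_id[network$nodes$role == "lncRNA"]

  screening <- stage("survival_screen", {
    if (length(net_lncs) == 0L) stopf("network contains no lncRNA to screen")
    sc <- screen_survival(expr, surv, genes = net_lncs,
                          minprop = config$minprop,
                          p_max = config$screen_p_max)
    note("stage=survival_screen lncRNAs=%d significant=%d",
         nrow(sc), sum(sc$significant, na.rm = TRUE))
    if (!is.null(outdir)) write_tsv(sc, out_path("survival_screen.tsv"), header)
    sc
  })

  fit <- stage("cox", {
    X <- t(expr$values[net_lncs, surv$sample_id, drop = FALSE])
    f <- cox_fit(X, surv)
    note("stage=cox covariates=%d events=%d converged=%s",
         ncol(X), f$n_event, f$converged)
    if (!is.null(outdir))
      write_tsv(cbind(gene_id = rownames(summary(f)), summary(f)),
                out_path("cox_fit.tsv"), header)
    f
  })

  sig_eval <- stage("signature", {
    sig <- tryCatch(
      build_signature(expr, surv, fit = fit, p_max = config$cox_p_max,
                      split = config$split, minprop = config$minprop),
      error = function(e) {
        note("stage=signature members=0 note=%s", conditionMessage(e))
        NULL
      })
    ev <- NULL
    if (!is.null(sig)) {
      ev <- evaluate_signature(sig, surv, horizon = config$roc_horizon)
      note("stage=signature members=%d split=%s mortality=%s auc=%.4f logrank_p=%.4g",
           nrow(sig$members), config$split,
           paste(sprintf("%.1f%%", 100 * ev$mortality_rate), collapse = "/"),
           ev$roc$auc, ev$logrank$p_value)
      if (!is.null(outdir))
        write_signature(sig, ev, out_path("signature_members.tsv"),
                        out_path("signature_scores.tsv"),
                        out_path("signature_roc.tsv"), header_line = header)
    }
    list(signature = sig, evaluation = ev)
  })

  hallmarks <- stage("hallmarks", {
    chart <- build_chart(network, dataset$gene_go, dataset$go_hallmark)
    assoc <- predict_associations(chart, strong_min = config$strong_min)
    note("stage=hallmarks associations=%d strong=%d rna_dropped=%d",
         nrow(assoc), sum(assoc$strong), chart$n_rna_dropped)
    if (!is.null(outdir))
      write_hallmarks(chart, assoc, out_path("hallmark_associations.tsv"),
                      out_path("hallmark_chart.tsv"), header_line = header)
    list(chart = chart, associations = assoc)
  })

  if (!is.null(outdir)) {
    writeLines(c(paste0("# ", header), log), file.path(outdir, "run_log.txt"))
    cfg_shown <- unclass(config)[setdiff(names(config), "outdir")]
    writeLines(c(paste0("# ", header),
                 utils::capture.output(utils::str(cfg_shown, give.attr = FALSE))),
               file.path(outdir, "config.txt"))
  }
  structure(list(dataset = dataset, de = de, candidates = candidates,
                 network = network, topology = topo$table,
                 power_law = topo$power_law, screening = screening,
                 fit = fit, signature = sig_eval$signature,
                 evaluation = sig_eval$evaluation,
                 chart = hallmarks$chart, associations = hallmarks$associations,
                 log = log, config = config, hash = hash),
            class = "lnc_pipeline")
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  cat("lncRNA-mRNA network & signature pipeline\n")
  cat(sprintf("  candidates: %d of %d genes pass the DE gate\n",
              length(x$candidates), nrow(x$de)))
  print(x$network)
  cat(sprintf("  screening: %d / %d lncRNAs associated with OS (p < %g)\n",
              sum(x$screening$significant, na.rm = TRUE), nrow(x$screening),
              x$config$screen_p_max))
  if (!is.null(x$signature)) {
    cat(sprintf("  signature: %s\n",
                paste(x$signature$members$gene_id, collapse = ", ")))
    cat(sprintf("  mortality High vs Low risk: %.2f%% vs %.2f%%; AUC = %.4f; log-rank p = %.4g\n",
                100 * x$evaluation$mortality_rate[["High-risk"]],
                100 * x$evaluation$mortality_rate[["Low-risk"]],
                x$evaluation$roc$auc, x$evaluation$logrank$p_value))
  } else cat("  signature: no lncRNA reached the Cox membership threshold\n")
  cat(sprintf("  hallmark associations: %d (%d strong)\n",
              nrow(x$associations), sum(x$associations$strong)))
  invisible(x)
}

#' @export
summary.lnc_pipeline <- function(object, ...) {
  list(n_genes = nrow(object$de),
       n_candidates = length(object$candidates),
       n_nodes = nrow(object$network$nodes),
       n_edges = nrow(object$network$edges),
       n_modules = if (nrow(object$network$nodes)) max(object$network$nodes$module) else 0L,
       max_degree = max(object$topology$degree),
       power_law_exponent = if (is.null(object$power_law)) NA_real_
                            else object$power_law$exponent,
       n_screen_significant = sum(object$screening$significant, na.rm = TRUE),
       signature_members = if (is.null(object$signature)) character(0)
                           else object$signature$members$gene_id,
       auc = if (is.null(object$evaluation)) NA_real_ else object$evaluation$roc$auc,
       logrank_p = if (is.null(object$evaluation)) NA_real_
                   else object$evaluation$logrank$p_value,
       mortality = if (is.null(object$evaluation)) NULL
                   else object$evaluation$mortality_rate,
       n_strong_associations = sum(object$associations$strong))
}
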