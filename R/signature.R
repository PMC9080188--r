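#' Build a multi-lncRNA risk signature from a multivariate Cox fit
#'
#' Fits (or reuses) a multivariate Cox model over the candidate lncRNAs and
#' keeps as signature members exactly the lncRNAs with Wald p strictly below
#' `p_max`. Each patient's risk score is the linear combination
#' `sum_i expression_i * beta_i` over the members, and patients are split into
#' Low-risk / High-risk groups at either the maximally selected cutpoint of
#' the scores (default) or the median (`split = "median"`, which always gives
#' a near-equal split).
#'
#' @param x an [expr_matrix] (log2 scale) containing the candidate lncRNAs.
#' @param s survival table; its `sample_id`s must be columns of `x`.
#' @param genes candidate lncRNAs fed to the Cox model; default all lncRNAs
#'   in `x`. Ignored when `fit` is supplied.
#' @param fit optional pre-computed [cox_fit()] whose covariates are genes of
#'   `x`.
#' @param p_max membership threshold on the Cox Wald p-value (strict <).
#' @param split `"cutpoint"` or `"median"`.
#' @param minprop minimum group proportion for the cutpoint scan.
#' @return Object of class `risk_signature`: `members` (data.frame
#'   `gene_id`, `beta`, `hazard_ratio`, `p_value`), `scores` (named per
#'   sample), `cutpoint`, `split`, `risk_group` (factor Low-risk/High-risk
#'   per sample), and the underlying `fit`.
#' @export
build_signature <- function(x, s, genes = NULL, fit = NULL, p_max = 0.05,
                            split = c("cutpoint", "median"), minprop = 0.1) {
  split <- match.arg(split)
  stopifnot(inherits(x, "expr_matrix"))
  s <- as_survival_table(s)
  missing_s <- setdiff(s$sample_id, colnames(x$values))
  if (length(missing_s)) stopf("survival samples not in matrix: %s",
                               paste(missing_s, collapse = ", "))
  if (is.null(fit)) {
    if (is.null(genes)) genes <- rownames(x$values)[x$role == "lncRNA"]
    if (length(genes) < 1L) stopf("no candidate lncRNAs")
    missing <- setdiff(genes, rownames(x$values))
    if (length(missing)) stopf("genes not in matrix: %s",
                               paste(missing, collapse = ", "))
    X <- t(x$values[genes, s$sample_id, drop = FALSE])
    fit <- cox_fit(X, s)
  } else {
    stopifnot(inherits(fit, "cox_fit"))
    missing <- setdiff(names(fit$coefficients), rownames(x$values))
    if (length(missing)) stopf("fit covariates not in matrix: %s",
                               paste(missing, collapse = ", "))
  }
  sel <- fit$p_value < p_max
  if (!any(sel))
    stopf("no lncRNA reaches Cox p < %g (minimum observed p = %.4g)",
          p_max, min(fit$p_value))
  members <- data.frame(gene_id = names(fit$coefficients)[sel],
                        beta = unname(fit$coefficients[sel]),
                        hazard_ratio = unname(fit$hazard_ratio[sel]),
                        p_value = unname(fit$p_value[sel]),
                        stringsAsFactors = FALSE)
  ex <- x$values[members$gene_id, s$sample_id, drop = FALSE]
  scores <- stats::setNames(as.numeric(crossprod(ex, members$beta)),
                            s$sample_id)
  if (split == "cutpoint") {
    cp <- optimal_cutpoint(scores, s, minprop = minprop)
    cut <- cp$cutpoint
  } else {
    cut <- stats::median(scores)
  }
  grp <- factor(ifelse(scores > cut, "High-risk", "Low-risk"),
                levels = c("Low-risk", "High-risk"))
  names(grp) <- s$sample_id
  structure(list(members = members, scores = scores, cutpoint = cut,
                 split = split, risk_group = grp, fit = fit),
            class = "risk_signature")
}

#' @export
print.risk_signature <- function(x, ...) {
  cat(sprintf("risk signature: %d lncRNA member(s), %s split at %.4g (%d Low-risk / %d High-risk)\n",
              nrow(x$members), x$split, x$cutpoint,
              sum(x$risk_group == "Low-risk"), sum(x$risk_group == "High-risk")))
  print(x$members)
  invisible(x)
}

#' Evaluate a risk signature against survival outcomes
#'
#' Compares the Low-risk and High-risk groups with a log-rank test, computes
#' per-group Kaplan-Meier curves and mortality rates (observed events /
#' subjects), and evaluates the risk score with a time-dependent ROC at the
#' given horizon.
#'
#' @param sig a [build_signature()] result.
#' @param s survival table (the samples the signature scored).
#' @param horizon ROC horizon in days; default the median observed time.
#' @return Object of class `signature_eval`: `logrank`, `mortality_rate`
#'   (named per group), `km` (list of `km_curve` per group), `roc`, `n`
#'   (per group).
#' @export
evaluate_signature <- function(sig, s, horizon = NULL) {
  stopifnot(inherits(sig, "risk_signature"))
  s <- as_survival_table(s)
  grp <- sig$risk_group[s$sample_id]
  if (any(is.na(grp))) stopf("signature has no risk group for some samples")
  if (length(unique(grp)) < 2L)
    stopf("degenerate split: all samples in one risk group")
  if (is.null(horizon)) horizon <- stats::median(s$time)
  lr <- logrank_test(s, grp)
  mort <- vapply(levels(grp), function(l) mean(s$event[grp == l]), numeric(1))
  km <- lapply(stats::setNames(levels(grp), levels(grp)),
               function(l) km_estimate(s[grp == l, , drop = FALSE]))
  roc <- td_roc(sig$scores[s$sample_id], s, horizon)
  structure(list(logrank = lr, mortality_rate = mort, km = km, roc = roc,
                 n = table(grp), horizon = horizon),
            class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf("signature evaluation (n = %s)\n",
              paste(sprintf("%s %d", names(x$n), x$n), collapse = ", ")))
  cat(sprintf("  mortality: %s\n",
              paste(sprintf("%s %.2f%%", names(x$mortality_rate),
                            100 * x$mortality_rate), collapse = " vs ")))
  cat(sprintf("  log-rank: chi-square = %.3f, p = %.4g\n",
              x$logrank$chi_square, x$logrank$p_value))
  cat(sprintf("  time-dependent AUC at t = %g: %.4f\n", x$horizon, x$roc$auc))
  invisible(x)
}

#' @export
plot.signature_eval <- function(x, which = c("km", "roc"), ...) {
  which <- match.arg(which)
  if (which == "km") {
    plot(x$km[[1L]], col = "turquoise3", ...)
    plot(x$km[[2L]], add = TRUE, col = "red3")
    graphics::legend("topright", legend = names(x$km), lty = 1,
                     col = c("turquoise3", "red3"), bty = "n")
  } else plot(x$roc, ...)
  invisible(x)
}

#' Export signature report tables
#'
#' Writes the member table (gene, beta, HR, p), the per-sample score/group
#' table, and the ROC points.
#'
#' @param sig a `risk_signature`.
#' @param eval a `signature_eval` (for the ROC points; optional).
#' @param member_path,score_path,roc_path output TSV paths (`NULL` to skip).
#' @param header_line optional `#` provenance line.
#' @return Invisibly, the paths written.
#' @export
write_signature <- function(sig, eval = NULL, member_path = NULL,
                            score_path = NULL, roc_path = NULL,
                            header_line = NULL) {
  written <- character(0)
  if (!is.null(member_path))
    written <- c(written, write_tsv(sig$members, member_path, header_line))
  if (!is.null(score_path)) {
    df <- data.frame(sample_id = names(sig$scores),
                     risk_score = unname(sig$scores),
                     risk_group = as.character(sig$risk_group[names(sig$scores)]),
                     stringsAsFactors = FALSE)
    written <- c(written, write_tsv(df, score_path, header_line))
  }
  if (!is.null(roc_path) && !is.null(eval)) {
    df <- data.frame(fpr = eval$roc$fpr, tpr = eval$roc$tpr)
    written <- c(written, write_tsv(df, roc_path, header_line))
  }
  invisible(written)
}
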