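#' Two-group differential expression on log2 values
#'
#' Per-gene tumor-vs-normal comparison on a log2-scale matrix: logFC is the
#' tumor minus normal mean, p-values come from a two-sided Welch (default) or
#' pooled-variance t-test, and FDR is the Benjamini-Hochberg adjustment over
#' all tested genes. The candidate gate flags genes with `fdr < fdr_max` and
#' `|logFC| > lfc_min` (both strict); set `gate_on = "p"` to gate on the raw
#' p-value instead of the FDR.
#'
#' A gene with zero variance in both groups is assigned p = 1 by convention
#' and flagged in the `degenerate` column.
#'
#' @param x an [expr_matrix] with `scale = "log2"` and at least two samples
#'   per group.
#' @param test `"welch"` or `"student"`.
#' @param fdr_max,lfc_min gate thresholds (defaults 0.05 and 2).
#' @param gate_on `"fdr"` (default) or `"p"`.
#' @return A data.frame of class `de_table`: `gene_id`, `role`, `logFC`,
#'   `p_value`, `fdr`, `passes_gate`, `degenerate`.
#' @export
differential_expression <- function(x, test = c("welch", "student"),
                                    fdr_max = 0.05, lfc_min = 2,
                                    gate_on = c("fdr", "p")) {
  test <- match.arg(test)
  gate_on <- match.arg(gate_on)
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2") stopf("differential_expression expects log2-scale values")
  tum <- x$group == "tumor"
  nrm <- x$group == "normal"
  if (sum(tum) < 2L || sum(nrm) < 2L)
    stopf("need at least 2 samples per group (got %d tumor, %d normal)",
          sum(tum), sum(nrm))
  vt <- x$values[, tum, drop = FALSE]
  vn <- x$values[, nrm, drop = FALSE]
  logfc <- rowMeans(vt) - rowMeans(vn)
  p <- numeric(nrow(vt))
  degen <- logical(nrow(vt))
  for (i in seq_len(nrow(vt))) {
    res <- tryCatch(
      stats::t.test(vt[i, ], vn[i, ],
                    var.equal = (test == "student"))$p.value,
      error = function(e) NA_real_)
    if (is.na(res)) { p[i] <- 1; degen[i] <- TRUE } else p[i] <- res
  }
  fdr <- bh_adjust(p)
  crit <- if (gate_on == "fdr") fdr else p
  out <- data.frame(gene_id = rownames(x$values),
                    role = unname(x$role),
                    logFC = unname(logfc),
                    p_value = p, fdr = fdr,
                    passes_gate = crit < fdr_max & abs(logfc) > lfc_min,
                    degenerate = degen,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("de_table", "data.frame"),
            fdr_max = fdr_max, lfc_min = lfc_min, gate_on = gate_on)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH-adjusted p-values (clipped to 1) in the input order. Thin
#' validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of the same length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must be finite numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select candidate network nodes from a DE table
#'
#' Genes with `fdr < fdr_max` and `|logFC| > lfc_min` (both strict), ordered
#' by ascending FDR then gene id. Relaxing either threshold never removes a
#' gene.
#'
#' @param de a `de_table` from [differential_expression()] (or any data.frame
#'   with `gene_id`, `logFC` and `fdr` columns).
#' @param fdr_max,lfc_min strict thresholds; defaults 0.05 and 2.
#' @return Character vector of gene ids.
#' @export
select_candidates <- function(de, fdr_max = 0.05, lfc_min = 2) {
  need <- c("gene_id", "logFC", "fdr")
  miss <- setdiff(need, colnames(de))
  if (length(miss)) stopf("DE table lacks column(s): %s", paste(miss, collapse = ", "))
  keep <- de$fdr < fdr_max & abs(de$logFC) > lfc_min
  sel <- de[keep, , drop = FALSE]
  sel$gene_id[order(sel$fdr, sel$gene_id)]
}

#' Read/write DE tables
#'
#' TSV schema: `gene_id`, `role`, `logFC`, `p_value`, `fdr`, `passes_gate`.
#' `read_de_table()` is the import path for an externally computed DE table
#' (e.g. from edgeR) in the same schema; `role` defaults to `"mRNA"` and
#' `passes_gate` is recomputed downstream if absent.
#'
#' @param path file path.
#' @param de a `de_table`.
#' @param header_line optional `#` provenance line for the writer.
#' @return `read_de_table()`: a `de_table`; `write_de_table()`: `path`.
#' @export
read_de_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "logFC", "p_value")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("%s lacks column(s): %s", path, paste(miss, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) stopf("%s: duplicated gene id", path)
  if (is.null(df$role)) df$role <- "mRNA"
  if (is.null(df$fdr)) df$fdr <- bh_adjust(df$p_value)
  if (is.null(df$passes_gate)) df$passes_gate <- df$fdr < 0.05 & abs(df$logFC) > 2
  if (is.null(df$degenerate)) df$degenerate <- FALSE
  structure(df, class = c("de_table", "data.frame"))
}

#' @rdname read_de_table
#' @export
write_de_table <- function(de, path, header_line = NULL) {
  write_tsv(as.data.frame(de), path, header_line)
}
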