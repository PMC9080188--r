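#' Expression matrix container
#'
#' A light container for a genes x samples expression matrix carrying, for each
#' gene, its RNA class (mRNA or lncRNA) and, for each sample, its group
#' (tumor or normal), together with the scale of the values (raw abundance or
#' log2-transformed).
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param role character vector of gene roles, one of `"mRNA"`/`"lncRNA"` per
#'   gene (recycled if length 1).
#' @param group character vector of sample groups, one of `"tumor"`/`"normal"`
#'   per sample (recycled if length 1).
#' @param scale `"raw"` for non-negative abundances (RSEM/RPKM-like) or
#'   `"log2"` for log2-transformed values.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `role` (named by gene), `group` (named by sample) and `scale`.
#' @export
expr_matrix <- function(values, role, group, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must have gene row names and sample column names")
  gid <- rownames(values)
  sid <- colnames(values)
  if (anyDuplicated(gid)) stopf("duplicate gene id: %s",
                                paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid)) stopf("duplicate sample id: %s",
                                paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (nrow(values) == 0L || ncol(values) == 0L) stopf("empty expression matrix")
  role <- rep_len(as.character(role), nrow(values))
  group <- rep_len(as.character(group), ncol(values))
  if (!all(role %in% c("mRNA", "lncRNA")))
    stopf("gene roles must be 'mRNA' or 'lncRNA'")
  if (!all(group %in% c("tumor", "normal")))
    stopf("sample groups must be 'tumor' or 'normal'")
  names(role) <- gid
  names(group) <- sid
  structure(list(values = values, role = role, group = group, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  genes:   %d mRNA, %d lncRNA\n",
              sum(x$role == "mRNA"), sum(x$role == "lncRNA")))
  cat(sprintf("  samples: %d tumor, %d normal\n",
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample ids of an expression matrix
#' @param x an [expr_matrix].
#' @return character vector of ids.
#' @export
genes <- function(x) rownames(x$values)

#' @rdname genes
#' @export
samples <- function(x) colnames(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an [expr_matrix].
#' @param genes,samples character vectors of ids to keep (default: all).
#' @return An [expr_matrix] restricted to the requested rows/columns.
#' @export
expr_subset <- function(x, genes = NULL, samples = NULL) {
  g <- if (is.null(genes)) rownames(x$values) else genes
  s <- if (is.null(samples)) colnames(x$values) else samples
  missing_g <- setdiff(g, rownames(x$values))
  if (length(missing_g)) stopf("unknown gene id: %s", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(s, colnames(x$values))
  if (length(missing_s)) stopf("unknown sample id: %s", paste(missing_s, collapse = ", "))
  expr_matrix(x$values[g, s, drop = FALSE], x$role[g], x$group[s], x$scale)
}
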