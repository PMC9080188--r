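#' Read an expression matrix from TSV
#'
#' Expected layout: tab-delimited, first column `gene_id`, remaining columns
#' one per sample, header row of sample ids. Lines starting with `#` are
#' ignored. Parsing is strict: ragged rows, duplicate gene or sample ids,
#' an empty matrix, or non-numeric cells are errors (never silent NA).
#'
#' @param path file path.
#' @param role RNA class to assign to every gene in the file
#'   (`"mRNA"` or `"lncRNA"`).
#' @param group sample group to assign (`"tumor"`, `"normal"`), or a named
#'   character vector keyed by sample id. Defaults to `"tumor"`; when the
#'   matrix is later merged with a sample annotation the groups are taken
#'   from the annotation instead.
#' @param scale scale of the stored values (`"raw"` or `"log2"`).
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, role = c("mRNA", "lncRNA"), group = "tumor",
                            scale = c("raw", "log2")) {
  role <- match.arg(role)
  scale <- match.arg(scale)
  if (!file.exists(path)) stopf("no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L) stopf("%s: empty file", path)
  if (length(unique(nf)) != 1L)
    stopf("%s: ragged rows (field counts %s)", path,
          paste(unique(nf), collapse = "/"))
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L) stopf("%s: empty expression matrix", path)
  gid <- df[[1L]]
  sid <- colnames(df)[-1L]
  if (anyDuplicated(gid))
    stopf("%s: duplicated gene id: %s", path,
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stopf("%s: duplicated sample id in header: %s", path,
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(sid), dimnames = list(gid, sid))
  for (j in seq_along(sid)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(trimws(col) %in% c("NA", "")))
    if (length(bad))
      stopf("%s: non-numeric value '%s' (gene %s, sample %s)",
            path, col[bad[1L]], gid[bad[1L]], sid[j])
    vals[, j] <- num
  }
  if (is.null(names(group))) grp <- rep_len(group, length(sid))
  else {
    missing <- setdiff(sid, names(group))
    if (length(missing)) stopf("no group for sample %s", paste(missing, collapse = ", "))
    grp <- unname(group[sid])
  }
  expr_matrix(vals, role = role, group = grp, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample.
#'
#' @param x an [expr_matrix].
#' @param path output file path.
#' @param header_line optional provenance comment written as a first `#` line.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, header_line = NULL) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, header_line)
}

#' Read a sample annotation table
#'
#' Columns: `sample_id`, `group` (tumor/normal), and optionally `os_time`
#' (overall-survival time in days, non-negative) and `os_event` (0 = censored,
#' 1 = death). Wherever `os_time` is present `os_event` must be too.
#'
#' @param path file path.
#' @return A validated data.frame.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  validate_annotation(df)
}

validate_annotation <- function(df) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("annotation: duplicated sample id: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$group %in% c("tumor", "normal")))
    stopf("annotation: group must be 'tumor' or 'normal'")
  if (is.null(df$os_time)) df$os_time <- NA_real_
  if (is.null(df$os_event)) df$os_event <- NA_integer_
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.integer(df$os_event)
  if (any(!is.na(df$os_time) & df$os_time < 0)) stopf("annotation: negative os_time")
  if (any(!is.na(df$os_event) & !df$os_event %in% 0:1))
    stopf("annotation: os_event must be 0 or 1")
  if (any(!is.na(df$os_time) & is.na(df$os_event)))
    stopf("annotation: os_time present without os_event")
  df
}

#' Merge mRNA and lncRNA expression profiles
#'
#' Row-concatenates the two matrices restricted to samples carrying both
#' profiles and present in the annotation (the triple intersection), in
#' canonical sorted sample order so downstream results do not depend on input
#' column order. Sample groups are taken from the annotation.
#'
#' @param mrna,lncrna [expr_matrix] objects on the same scale.
#' @param annot sample annotation data.frame (see [read_annotation()]).
#' @return An [expr_matrix] over the merged gene set and common samples.
#' @export
merge_profiles <- function(mrna, lncrna, annot) {
  annot <- validate_annotation(annot)
  if (mrna$scale != lncrna$scale)
    stopf("cannot merge: mRNA matrix is %s-scale, lncRNA matrix is %s-scale",
          mrna$scale, lncrna$scale)
  both <- intersect(rownames(mrna$values), rownames(lncrna$values))
  if (length(both))
    stopf("gene id present in both inputs (ambiguous role): %s",
          paste(both, collapse = ", "))
  common <- sort(intersect(intersect(colnames(mrna$values), colnames(lncrna$values)),
                           annot$sample_id))
  if (length(common) == 0L)
    stopf("no sample carries both mRNA and lncRNA profiles and an annotation")
  vals <- rbind(mrna$values[, common, drop = FALSE],
                lncrna$values[, common, drop = FALSE])
  role <- c(rep("mRNA", nrow(mrna$values)), rep("lncRNA", nrow(lncrna$values)))
  grp <- annot$group[match(common, annot$sample_id)]
  expr_matrix(vals, role = role, group = grp, scale = mrna$scale)
}

#' Preprocess a raw expression matrix
#'
#' Drops genes whose abundance is zero in every sample, then applies
#' `log2(value + pseudocount)`. Mirrors the usual treatment of RSEM/RPKM
#' abundances before correlation analysis.
#'
#' @param x an [expr_matrix] with `scale = "raw"` and non-negative values.
#' @param pseudocount added before the log; default 1 so that zeros map to 0.
#' @return An [expr_matrix] with `scale = "log2"`.
#' @export
preprocess <- function(x, pseudocount = 1) {
  if (x$scale != "raw") stopf("preprocess expects a raw-scale matrix")
  if (any(x$values < 0, na.rm = TRUE)) stopf("negative raw expression values")
  if (!is.numeric(pseudocount) || pseudocount < 0) stopf("invalid pseudocount")
  keep <- rowSums(x$values != 0, na.rm = TRUE) > 0
  if (!any(keep)) stopf("all genes are zero in every sample")
  vals <- log2(x$values[keep, , drop = FALSE] + pseudocount)
  expr_matrix(vals, x$role[keep], x$group, scale = "log2")
}
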