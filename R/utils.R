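# internal helpers

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Cheap deterministic fingerprint of an R object (for output provenance lines).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 7
  for (i in seq_along(b)) h <- (h * 31 + b[[i]]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min
}

# Write a data.frame as the package's TSV dialect, with an optional comment header.
write_tsv <- function(df, path, header_line = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_line)) writeLines(paste0("# ", header_line), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, check.names = FALSE, quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}
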