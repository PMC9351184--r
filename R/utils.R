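#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dhyper median p.adjust pnorm rbinom rbeta runif ave setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Tab-separated I/O used for every table the pipeline reads or writes.
## Plain read.delim/write.table with conventions fixed in one place so that
## write -> read round-trips are exact.
read_tsv <- function(path, header = TRUE, col_names = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, header = header, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "", quote = "")
  if (!is.null(col_names)) {
    if (ncol(df) < length(col_names)) {
      stopf("%s: expected at least %d columns, found %d",
            path, length(col_names), ncol(df))
    }
    names(df)[seq_along(col_names)] <- col_names
  }
  df
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## site identity key used across modules: sites match on (chrom, pos, strand)
site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

check_strand <- function(strand, where = "strand") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stopf("%s must be '+' or '-' (offending value: '%s')",
          where, strand[which(bad)[1]])
  }
  invisible(strand)
}
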