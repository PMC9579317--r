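# Whitespace token reader for the block-structured plain-text input
# dialects.  Lines beginning with '#' (or trailing '#' comments) are
# ignored; tokens keep their source line number so parse errors can cite it.

token_reader <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- strsplit(trimws(lines), "[ \t,]+")
  lineno <- rep(seq_along(toks), lengths(toks))
  toks <- unlist(toks, use.names = FALSE)
  keep <- nzchar(toks)
  toks <- toks[keep]
  lineno <- lineno[keep]
  pos <- 0L

  take <- function(n = 1L, what = "token") {
    if (pos + n > length(toks)) {
      stop(sprintf("unexpected end of file '%s' while reading %s (after line %d)",
                   file, what,
                   if (length(lineno)) lineno[length(lineno)] else 0L),
           call. = FALSE)
    }
    out <- toks[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  take_num <- function(n = 1L, what = "number") {
    raw <- take(n, what)
    out <- suppressWarnings(as.numeric(raw))
    if (anyNA(out)) {
      bad <- which(is.na(out))[1L]
      stop(sprintf("line %d of '%s': expected %s, got '%s'",
                   lineno[pos - n + bad], file, what, raw[bad]), call. = FALSE)
    }
    out
  }
  take_int <- function(n = 1L, what = "integer") {
    out <- take_num(n, what)
    if (any(out != round(out))) {
      stop(sprintf("'%s': expected %s, got non-integer value", file, what),
           call. = FALSE)
    }
    as.integer(out)
  }
  list(take = take, take_num = take_num, take_int = take_int,
       exhausted = function() pos >= length(toks),
       line = function() if (pos > 0) lineno[pos] else 0L)
}

# Tab-separated writer used by all text outputs.
write_tsv <- function(df, file, append = FALSE, col.names = !append) {
  suppressWarnings(  # write.table warns when appending under a header
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = col.names, append = append))
}

write_lines <- function(x, file, append = FALSE) {
  cat(paste0(x, "\n", collapse = ""), file = file, append = append)
}

#' Output file naming scheme
#'
#' Group outputs are named \code{<prefix>.<group>.<ext>} where the group tag
#' is one of pil, ib1, ib2, if2 (independent analyses) or ibc, ifl, ibl,
#' ibf, bfl (combined designs); outputs not tied to a mapping group use
#' \code{<prefix>.<ext>}.
#'
#' @param prefix output path prefix (input file stem).
#' @param group group tag, or \code{"common"} for ungrouped outputs.
#' @param ext three-character extension code.
#' @return the output file path.
#' @export
output_name <- function(prefix, group, ext) {
  group <- tolower(group)
  valid <- c("pil", "ib1", "ib2", "if2", "ibc", "ifl", "ibl", "ibf", "bfl", "common")
  if (!group %in% valid) stop("unknown output group tag: ", group)
  if (group == "common") paste0(prefix, ".", ext) else paste0(prefix, ".", group, ".", ext)
}
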