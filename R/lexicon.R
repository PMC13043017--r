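#' Construct a tone lexicon
#'
#' A tone lexicon is two disjoint term sets: polite/empathy-related terms and
#' harsh/legalistic terms. The tone-friendliness score counts occurrences of
#' each category per document, so a term appearing in both lists would make
#' the score's sign ambiguous — overlap is an error, not a warning.
#'
#' @param polite Character vector of polite/empathy terms.
#' @param harsh Character vector of harsh terms.
#' @return An object of class `icf_lexicon`: a list with sorted, de-duplicated
#'   `polite` and `harsh` character vectors.
#' @export
#' @examples
#' lexicon(polite = c("please", "thanks"), harsh = c("must", "forbidden"))
lexicon <- function(polite, harsh) {
  polite <- unique(trimws(as.character(polite)))
  harsh <- unique(trimws(as.character(harsh)))
  polite <- polite[nzchar(polite)]
  harsh <- harsh[nzchar(harsh)]
  if (length(polite) == 0) abort_validation("polite term list is empty")
  if (length(harsh) == 0) abort_validation("harsh term list is empty")
  both <- intersect(polite, harsh)
  if (length(both) > 0) {
    abort_validation(sprintf(
      "term(s) present in both polite and harsh lists: %s",
      paste(both, collapse = ", ")
    ))
  }
  structure(
    list(polite = sort(polite), harsh = sort(harsh)),
    class = "icf_lexicon"
  )
}

#' Read a tone lexicon from term-list files
#'
#' Each file holds one term per line, UTF-8; blank lines and lines starting
#' with `#` are skipped; duplicate terms within a list collapse to one.
#'
#' @param polite_path,harsh_path Paths to the two term lists.
#' @return An `icf_lexicon`, see [lexicon()].
#' @export
read_lexicon <- function(polite_path, harsh_path) {
  lexicon(read_term_list(polite_path), read_term_list(harsh_path))
}

read_term_list <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("lexicon file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @export
print.icf_lexicon <- function(x, ...) {
  cat(sprintf(
    "<icf_lexicon> %d polite term(s), %d harsh term(s)\n",
    length(x$polite), length(x$harsh)
  ))
  invisible(x)
}
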