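#' Read a document corpus from a manifest
#'
#' A corpus is a set of document versions indexed by a three-column delimited
#' manifest with header `doc_id, version, path`. Each `path` (relative paths
#' are resolved against the manifest's directory) must point to a UTF-8
#' plain-text file holding one version of one document.
#'
#' @param manifest_path Path to the manifest CSV/TSV (delimiter sniffed from
#'   the header line).
#' @param versions Optional character vector of expected version labels; when
#'   given, any other label in the manifest is an error.
#' @param complete When `TRUE`, require every `doc_id` to be present for every
#'   version in `versions` (or every version observed, if `versions` is
#'   `NULL`).
#' @return A tibble with columns `doc_id`, `version`, `text` — one row per
#'   document version. `(doc_id, version)` pairs are unique and every `text`
#'   is non-empty after whitespace stripping.
#' @export
#' @seealso [write_corpus()], [compute_text_metrics()]
read_corpus <- function(manifest_path, versions = NULL, complete = FALSE) {
  manifest <- read_manifest(manifest_path)
  base_dir <- dirname(manifest_path)

  dup <- duplicated(manifest[c("doc_id", "version")])
  if (any(dup)) {
    bad <- manifest[dup, , drop = FALSE]
    abort_validation(sprintf(
      "duplicate (doc_id, version) in manifest: %s",
      paste(sprintf("(%s, %s)", bad$doc_id, bad$version), collapse = "; ")
    ))
  }
  if (!is.null(versions)) {
    unknown <- setdiff(unique(manifest$version), versions)
    if (length(unknown) > 0) {
      abort_validation(sprintf(
        "manifest uses version label(s) outside the configured set: %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }

  texts <- vapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$path[i]
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(base_dir, path)
    if (!file.exists(path)) {
      abort_io(sprintf(
        "manifest row %d (doc_id=%s, version=%s): file not found: %s",
        i, manifest$doc_id[i], manifest$version[i], path
      ))
    }
    raw <- readBin(path, what = "raw", n = file.size(path))
    txt <- rawToChar(raw)
    Encoding(txt) <- "UTF-8"
    if (!validUTF8(txt)) {
      abort_io(sprintf(
        "manifest row %d (doc_id=%s, version=%s): file is not valid UTF-8: %s",
        i, manifest$doc_id[i], manifest$version[i], path
      ))
    }
    txt
  }, character(1))

  empty <- !nzchar(trimws(texts))
  if (any(empty)) {
    abort_validation(sprintf(
      "document text is empty after whitespace stripping for: %s",
      paste(sprintf("(%s, %s)", manifest$doc_id[empty], manifest$version[empty]),
            collapse = "; ")
    ))
  }

  corpus <- tibble::tibble(
    doc_id = manifest$doc_id,
    version = manifest$version,
    text = texts
  )
  if (isTRUE(complete)) {
    check_corpus_complete(corpus, versions %||% unique(corpus$version))
  }
  corpus
}

read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort_io(sprintf("manifest not found: %s", manifest_path))
  }
  header <- readLines(manifest_path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  manifest <- utils::read.table(
    manifest_path,
    header = TRUE, sep = sep, quote = "\"",
    colClasses = "character", encoding = "UTF-8",
    stringsAsFactors = FALSE
  )
  assert_columns(manifest, c("doc_id", "version", "path"), "corpus manifest")
  manifest
}

check_corpus_complete <- function(corpus, versions) {
  grid <- expand.grid(
    doc_id = unique(corpus$doc_id), version = versions,
    stringsAsFactors = FALSE
  )
  key <- paste(corpus$doc_id, corpus$version, sep = "\r")
  missing <- grid[!paste(grid$doc_id, grid$version, sep = "\r") %in% key, ]
  if (nrow(missing) > 0) {
    abort_validation(sprintf(
      "corpus is incomplete; missing: %s",
      paste(sprintf("(%s, %s)", missing$doc_id, missing$version), collapse = "; ")
    ))
  }
  invisible(corpus)
}

#' Write a corpus to disk as text files plus a manifest
#'
#' The inverse of [read_corpus()]: one UTF-8 text file per document version
#' under `dir`, indexed by `manifest.csv`. Useful for materialising synthetic
#' corpora so they exercise the same readers as real data.
#'
#' @param corpus A tibble with `doc_id`, `version`, `text`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  assert_columns(corpus, c("doc_id", "version", "text"), "corpus")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%s.txt", corpus$doc_id, corpus$version)
  for (i in seq_len(nrow(corpus))) {
    con <- file(file.path(dir, files[i]), open = "wb")
    writeBin(charToRaw(enc2utf8(corpus$text[i])), con)
    close(con)
  }
  manifest <- data.frame(
    doc_id = corpus$doc_id, version = corpus$version, path = files,
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(manifest_path)
}
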