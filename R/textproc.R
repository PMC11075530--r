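#' Tokenize text into lowercased word tokens
#'
#' Tokens are maximal runs of letters/digits, optionally joined by internal
#' apostrophes or hyphens (`"state-of-the-art"` is one token). Punctuation is
#' discarded and everything is lowercased. The rule is deliberately simple and
#' fully specified so that results are reproducible; an alternative tokenizer
#' can be swapped in through the `token_regex` configuration option.
#'
#' @param text character scalar (may be empty).
#' @param token_regex Perl regular expression defining a token.
#' @return character vector of tokens in original order (length 0 for empty
#'   or token-free text).
#' @examples
#' tokenize("The cat sat.")
#' @export
tokenize <- function(text,
                     token_regex = "[\\p{L}\\p{N}]+(?:['-][\\p{L}\\p{N}]+)*") {
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr(token_regex, tolower(text), perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  substring(tolower(text), m, m + attr(m, "match.length") - 1L)
}

#' Split a token vector into consecutive fixed-size chunks
#'
#' Tokens are grouped into consecutive, non-overlapping chunks of
#' `chunk_size` tokens (default 25). A trailing remainder of `r` tokens forms
#' its own chunk when `r >= chunk_size / 2` and is otherwise merged into the
#' preceding chunk, so no chunk is ever shorter than half the nominal size
#' (the mean embedding of a near-empty chunk would be high-variance). The
#' remainder rule is configurable.
#'
#' @param tokens character vector of tokens in document order.
#' @param chunk_size positive integer, nominal tokens per chunk.
#' @param remainder `"merge"` (default), `"keep"` (remainder always its own
#'   chunk), or `"drop"` (remainder discarded).
#' @param doc_id optional document identifier carried on the result.
#' @return object of class `chunk_sequence`: list with `doc_id`, `chunks`
#'   (list of token vectors), `chunk_size`.
#' @examples
#' length(chunk_tokens(as.character(1:40), 25)$chunks)  # 2 chunks: 25 + 15
#' @export
chunk_tokens <- function(tokens, chunk_size = 25L,
                         remainder = c("merge", "keep", "drop"),
                         doc_id = NULL) {
  remainder <- match.arg(remainder)
  stopifnot(chunk_size >= 1)
  n <- length(tokens)
  if (n == 0L) {
    return(structure(list(doc_id = doc_id, chunks = list(),
                          chunk_size = as.integer(chunk_size)),
                     class = "chunk_sequence"))
  }
  full <- n %/% chunk_size
  r <- n %% chunk_size
  idx <- if (full > 0) rep(seq_len(full), each = chunk_size) else integer(0)
  if (r > 0) {
    tail_id <- switch(remainder,
      keep = full + 1L,
      drop = if (full == 0L) 1L else NA_integer_,
      merge = if (full == 0L || r >= chunk_size / 2) full + 1L else full)
    idx <- c(idx, rep(tail_id, r))
  }
  keep <- !is.na(idx)
  chunks <- unname(split(tokens[keep], idx[keep]))
  structure(list(doc_id = doc_id, chunks = chunks,
                 chunk_size = as.integer(chunk_size)),
            class = "chunk_sequence")
}

#' @export
print.chunk_sequence <- function(x, ...) {
  cat(sprintf("<chunk_sequence%s: %d chunks of nominal size %d>\n",
              if (is.null(x$doc_id)) "" else paste0(" ", x$doc_id),
              length(x$chunks), x$chunk_size))
  invisible(x)
}

#' Read a corpus from delimited text or record-per-line JSON
#'
#' Required columns/fields: `doc_id`, `author_id`, `text`. All other columns
#' are carried through as covariates. Delimited files must be UTF-8 with a
#' header row; quoted fields are handled. `format = "auto"` infers JSONL from
#' a `.jsonl`/`.ndjson` extension or a leading `{`.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"jsonl"`.
#' @return data.frame with one row per document.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
      "jsonl"
    } else if (grepl("^\\s*\\{", readLines(path, n = 1L, warn = FALSE))) {
      "jsonl"
    } else if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  df <- if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop(sprintf(
                        "unreadable JSON record %d in '%s': %s",
                        i, path, conditionMessage(e)), call. = FALSE))
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    data.table::setDF(data.table::rbindlist(recs, fill = TRUE))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    data.table::setDF(data.table::fread(path, sep = sep, header = TRUE,
                                        encoding = "UTF-8", data.table = FALSE))
  }
  req <- c("doc_id", "author_id", "text")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(sprintf("corpus '%s' lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$doc_id <- as.character(df$doc_id)
  df$author_id <- as.character(df$author_id)
  df$text <- as.character(df$text)
  df$text[is.na(df$text)] <- ""
  if (anyDuplicated(df$doc_id)) {
    stop(sprintf("duplicate doc_id in corpus: %s",
                 paste(unique(df$doc_id[duplicated(df$doc_id)]), collapse = ", ")),
         call. = FALSE)
  }
  df
}

# Optional stopword removal, used by the pipeline when a stopword file is
# configured. One stopword per line, matched after lowercasing.
read_stopwords <- function(path) {
  sw <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  tolower(sw[nzchar(sw)])
}
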