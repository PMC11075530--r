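#' Construct an embedding store from a word-vector matrix
#'
#' The store is a plain interface: a `vocab` of words and a numeric matrix
#' with one row per word. Any source of vectors (a word2vec file, the
#' deterministic hash store from the synthetic module, a user matrix) can
#' stand behind it.
#'
#' @param vectors numeric matrix with one row per word; rownames are words.
#' @return object of class `embedding_store` with fields `vocab`, `vectors`,
#'   `dim`.
#' @export
embedding_store <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors), !is.null(rownames(vectors)))
  structure(list(vocab = rownames(vectors), vectors = vectors,
                 dim = ncol(vectors)),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store: %d words, dimension %d>\n",
              length(x$vocab), x$dim))
  invisible(x)
}

#' Read word vectors in the word2vec interchange format
#'
#' Supports the two conventional layouts: text (header line `"V D"` then one
#' `word v1 ... vD` line per word, UTF-8, space-delimited) and binary (the
#' same header, then each word as bytes terminated by a space followed by D
#' little-endian 4-byte floats). Duplicate words keep the first vector, with
#' a warning; a malformed header or an entry with the wrong number of values
#' is an error.
#'
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @return an [embedding_store()].
#' @export
read_word2vec <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
      stop(sprintf("malformed word2vec header in '%s': '%s'", path, lines[1]),
           call. = FALSE)
    }
    V <- as.integer(hdr[1]); D <- as.integer(hdr[2])
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (length(body) != V) {
      stop(sprintf("word2vec file '%s' declares %d entries but has %d",
                   path, V, length(body)), call. = FALSE)
    }
    parts <- strsplit(trimws(body), "\\s+")
    words <- vapply(parts, `[`, character(1), 1L)
    bad <- which(lengths(parts) != D + 1L)
    if (length(bad)) {
      stop(sprintf("entry '%s' in '%s' has %d values, expected %d",
                   words[bad[1]], path, lengths(parts)[bad[1]] - 1L, D),
           call. = FALSE)
    }
    vec <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                  nrow = V, ncol = D, byrow = TRUE)
    if (anyNA(vec)) stop(sprintf("non-numeric vector value in '%s'", path),
                         call. = FALSE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    read_token <- function(stop_chars) {
      out <- raw(0)
      repeat {
        b <- readBin(con, "raw", n = 1L)
        if (length(b) == 0L) stop(sprintf("unexpected end of file in '%s'", path),
                                  call. = FALSE)
        if (rawToChar(b) %in% stop_chars) {
          if (length(out) == 0L && rawToChar(b) == "\n") next # tolerate newlines
          return(rawToChar(out))
        }
        out <- c(out, b)
      }
    }
    hdr_line <- read_token("\n")
    hdr <- strsplit(trimws(hdr_line), "\\s+")[[1]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
      stop(sprintf("malformed word2vec header in '%s': '%s'", path, hdr_line),
           call. = FALSE)
    }
    V <- as.integer(hdr[1]); D <- as.integer(hdr[2])
    words <- character(V)
    vec <- matrix(NA_real_, nrow = V, ncol = D)
    for (i in seq_len(V)) {
      words[i] <- read_token(" ")
      v <- readBin(con, "numeric", n = D, size = 4L, endian = "little")
      if (length(v) != D) {
        stop(sprintf("entry '%s' in '%s' is truncated", words[i], path),
             call. = FALSE)
      }
      vec[i, ] <- v
    }
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning(sprintf("%d duplicate word(s) in '%s'; first vector retained (e.g. '%s')",
                    sum(dup), path, words[dup][1]), call. = FALSE)
    vec <- vec[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  rownames(vec) <- words
  embedding_store(vec)
}

#' Write an embedding store in word2vec format
#'
#' Inverse of [read_word2vec()]; mostly used to exchange synthetic stores
#' with other tools and to exercise the readers in tests.
#'
#' @param store an [embedding_store()].
#' @param path output file path.
#' @param format `"text"` or `"binary"`.
#' @export
write_word2vec <- function(store, path, format = c("text", "binary")) {
  format <- match.arg(format)
  V <- length(store$vocab)
  D <- store$dim
  if (format == "text") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("%d %d", V, D), con)
    for (i in seq_len(V)) {
      writeLines(paste(store$vocab[i],
                       paste(sprintf("%.8g", store$vectors[i, ]), collapse = " ")),
                 con)
    }
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeBin(charToRaw(sprintf("%d %d\n", V, D)), con)
    for (i in seq_len(V)) {
      writeBin(charToRaw(paste0(store$vocab[i], " ")), con)
      writeBin(as.numeric(store$vectors[i, ]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Embed one chunk as the mean of its in-vocabulary token vectors
#'
#' Out-of-vocabulary tokens are skipped. A chunk with no in-vocabulary token
#' returns `NULL` ("empty"), which [embed_document()] counts in
#' `dropped_chunks` -- distinct from a zero vector.
#'
#' @param chunk character vector of tokens.
#' @param store an [embedding_store()].
#' @return numeric vector of length `store$dim`, or `NULL`.
#' @export
embed_chunk <- function(chunk, store) {
  idx <- match(chunk, store$vocab)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(NULL)
  colMeans(store$vectors[idx, , drop = FALSE])
}

#' Embed a chunk sequence as a semantic path
#'
#' Maps each chunk to a point with [embed_chunk()]; all-out-of-vocabulary
#' chunks are dropped (counted, never silently). Documents that end up with
#' fewer than 2 points are flagged `"too_short_for_speed"`, fewer than 3
#' additionally `"too_short_for_circuitousness"`; flags, not errors, so a
#' corpus always processes to completion.
#'
#' @param chunks a `chunk_sequence` (or plain list of token vectors).
#' @param store an [embedding_store()].
#' @return object of class `semantic_path`: list with `doc_id`, `points`
#'   (T x D matrix), `T`, `dropped_chunks`, `flags`.
#' @export
embed_document <- function(chunks, store) {
  doc_id <- if (inherits(chunks, "chunk_sequence")) chunks$doc_id else NULL
  chunk_list <- if (inherits(chunks, "chunk_sequence")) chunks$chunks else chunks
  pts <- lapply(chunk_list, embed_chunk, store = store)
  dropped <- sum(vapply(pts, is.null, logical(1)))
  pts <- pts[!vapply(pts, is.null, logical(1))]
  points <- if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(0), nrow = 0, ncol = store$dim)
  semantic_path(points, doc_id = doc_id, dropped_chunks = dropped)
}

#' Construct a semantic path from a point matrix
#'
#' @param points numeric T x D matrix, one ordered row per chunk.
#' @param doc_id optional identifier.
#' @param dropped_chunks number of chunks lost to out-of-vocabulary tokens.
#' @return object of class `semantic_path`.
#' @export
semantic_path <- function(points, doc_id = NULL, dropped_chunks = 0L) {
  stopifnot(is.matrix(points), is.numeric(points))
  T <- nrow(points)
  flags <- character(0)
  if (T < 2L) flags <- c(flags, "too_short_for_speed")
  if (T < 3L) flags <- c(flags, "too_short_for_circuitousness")
  structure(list(doc_id = doc_id, points = points, T = T,
                 dropped_chunks = as.integer(dropped_chunks), flags = flags),
            class = "semantic_path")
}

#' @export
print.semantic_path <- function(x, ...) {
  cat(sprintf("<semantic_path%s: T = %d points in %d dimensions%s>\n",
              if (is.null(x$doc_id)) "" else paste0(" ", x$doc_id),
              x$T, ncol(x$points),
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

as_point_matrix <- function(x) {
  if (inherits(x, "semantic_path")) x$points
  else if (is.matrix(x)) x
  else stop("expected a semantic_path or a point matrix", call. = FALSE)
}
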