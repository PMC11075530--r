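#' Run configuration
#'
#' Collects every tunable of the document-to-feature pipeline in one object.
#' The full configuration is serialized into every output table header so a
#' run can be reproduced from its artifacts alone.
#'
#' @param chunk_size tokens per chunk (default 25).
#' @param remainder trailing-chunk rule, see [chunk_tokens()].
#' @param volume_mode volume normalization, see [normalized_volume()].
#' @param exact_max largest interior-point count solved exactly (default 12;
#'   the Held-Karp table for 12 interior points is ~4096 x 12 doubles and
#'   solves in well under a second, while typical 22-point documents fall
#'   through to the heuristic).
#' @param restarts random restarts for the heuristic solver.
#' @param seed integer seed used by every stochastic component.
#' @param rank_tol relative singular-value cutoff for the affine-hull rank.
#' @param mvee_tol Khachiyan convergence tolerance.
#' @param mvee_max_iter Khachiyan iteration cap.
#' @param aggregate per-author aggregation: `"mean_of_z"` (average the
#'   corpus-standardized document features, the default) or `"z_of_mean"`
#'   (standardize the per-author mean of the log features).
#' @param token_regex tokenizer override, see [tokenize()].
#' @param stopword_file optional path to a one-per-line stopword list;
#'   stopwords are kept when `NULL` (the default).
#' @param unit_norm normalize token vectors to unit length before averaging
#'   (off by default).
#' @return object of class `topo_config` (a named list).
#' @export
topo_config <- function(chunk_size = 25L,
                        remainder = c("merge", "keep", "drop"),
                        volume_mode = c("dim_root", "per_chunk", "raw"),
                        exact_max = 12L,
                        restarts = 10L,
                        seed = 42L,
                        rank_tol = 1e-9,
                        mvee_tol = 1e-7,
                        mvee_max_iter = 50000L,
                        aggregate = c("mean_of_z", "z_of_mean"),
                        token_regex = "[\\p{L}\\p{N}]+(?:['-][\\p{L}\\p{N}]+)*",
                        stopword_file = NULL,
                        unit_norm = FALSE) {
  cfg <- list(chunk_size = as.integer(chunk_size),
              remainder = match.arg(remainder),
              volume_mode = match.arg(volume_mode),
              exact_max = as.integer(exact_max),
              restarts = as.integer(restarts),
              seed = as.integer(seed),
              rank_tol = rank_tol,
              mvee_tol = mvee_tol,
              mvee_max_iter = as.integer(mvee_max_iter),
              aggregate = match.arg(aggregate),
              token_regex = token_regex,
              stopword_file = stopword_file,
              unit_norm = isTRUE(unit_norm))
  stopifnot(cfg$chunk_size >= 1L, cfg$exact_max >= 0L, cfg$restarts >= 0L)
  structure(cfg, class = "topo_config")
}

#' @export
print.topo_config <- function(x, ...) {
  cat("<topo_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-14s %s\n", k, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

feature_cols <- c("speed", "norm_volume", "min_required_speed", "circuitousness")

# Internal: features for a list of token vectors; shared by process_corpus
# and the corpus generator so both measure documents identically.
features_for_tokens <- function(token_list, doc_ids, store, config) {
  stopwords <- if (!is.null(config$stopword_file)) {
    read_stopwords(config$stopword_file)
  } else NULL
  vectors <- store$vectors
  if (config$unit_norm) {
    nrm <- sqrt(rowSums(vectors^2))
    nrm[nrm == 0] <- 1
    vectors <- vectors / nrm
  }
  n <- length(token_list)
  # preallocated columns: this loop is the corpus-scale hot path
  col_T <- integer(n); col_d <- rep(NA_integer_, n)
  col_speed <- rep(NA_real_, n); col_rawv <- rep(NA_real_, n)
  col_normv <- rep(NA_real_, n); col_msp <- rep(NA_real_, n)
  col_circ <- rep(NA_real_, n); col_solver <- rep(NA_character_, n)
  col_dropped <- integer(n); col_flag <- character(n)
  for (i in seq_len(n)) {
    tokens <- token_list[[i]]
    if (!is.null(stopwords)) tokens <- tokens[!(tokens %in% stopwords)]
    if (length(tokens) == 0L) {
      col_flag[i] <- "empty_document"
      next
    }
    cs <- chunk_tokens(tokens, chunk_size = config$chunk_size,
                       remainder = config$remainder, doc_id = doc_ids[i])
    # chunk means in one pass: one lookup per token, grouped sums in C++
    idx <- match(tokens, store$vocab)
    idx[is.na(idx)] <- 0L
    chunk_id <- rep(seq_along(cs$chunks), lengths(cs$chunks))
    cm <- cpp_chunk_means(vectors, idx, chunk_id, length(cs$chunks))
    counts <- as.integer(cm$counts)
    surviving <- which(counts > 0L)
    dropped <- length(cs$chunks) - length(surviving)
    points <- if (length(surviving)) {
      cm$sums[surviving, , drop = FALSE] / counts[surviving]
    } else {
      matrix(numeric(0), nrow = 0, ncol = store$dim)
    }
    path <- semantic_path(points, doc_id = doc_ids[i], dropped_chunks = dropped)
    f <- extract_features(path, config)
    col_T[i] <- f$T; col_d[i] <- f$d
    col_speed[i] <- f$speed; col_rawv[i] <- f$raw_volume
    col_normv[i] <- f$norm_volume; col_msp[i] <- f$min_required_speed
    col_circ[i] <- f$circuitousness; col_solver[i] <- f$solver
    col_dropped[i] <- f$dropped_chunks
    col_flag[i] <- paste(f$flags, collapse = ";")
  }
  data.frame(doc_id = doc_ids, T = col_T, d = col_d, speed = col_speed,
             raw_volume = col_rawv, norm_volume = col_normv,
             min_required_speed = col_msp, circuitousness = col_circ,
             solver = col_solver, dropped_chunks = col_dropped,
             flag = col_flag, stringsAsFactors = FALSE)
}

#' Process a corpus into a per-document feature table
#'
#' Runs the full pipeline for every document -- tokenize, chunk, embed,
#' topography features -- then flags degenerate rows, log-transforms, and
#' corpus-standardizes the features. Every input document appears exactly
#' once in the output, valid or flagged; per-document values do not depend
#' on row order.
#'
#' @param corpus data.frame with `doc_id`, `author_id`, `text` and optional
#'   covariate columns (see [read_corpus()]).
#' @param store an [embedding_store()].
#' @param config a [topo_config()].
#' @param standardize add log and corpus-standardized columns (default TRUE).
#' @param verbose print a run summary.
#' @return data.frame with one row per document: identifiers, `T`, `d`, the
#'   four features, `solver`, `flag`, pass-through covariates, and (when
#'   `standardize`) their `log_` and `z_log_` variants. The configuration is
#'   attached as attribute `"config"`.
#' @export
process_corpus <- function(corpus, store, config = topo_config(),
                           standardize = TRUE, verbose = FALSE) {
  req <- c("doc_id", "author_id", "text")
  stopifnot(all(req %in% names(corpus)))
  if (anyDuplicated(corpus$doc_id)) stop("duplicate doc_id in corpus", call. = FALSE)
  token_list <- lapply(corpus$text, tokenize, token_regex = config$token_regex)
  feats <- features_for_tokens(token_list, corpus$doc_id, store, config)
  feats$author_id <- corpus$author_id[match(feats$doc_id, corpus$doc_id)]
  # degenerate but unflagged rows (zero speed or volume) cannot be logged
  degen <- feats$flag == "" &
    (!is.finite(feats$speed) | feats$speed <= 0 |
       !is.finite(feats$norm_volume) | feats$norm_volume <= 0)
  feats$flag[degen] <- "degenerate"
  covar <- setdiff(names(corpus), c(req))
  for (cv in covar) feats[[cv]] <- corpus[[cv]][match(feats$doc_id, corpus$doc_id)]
  front <- c("doc_id", "author_id")
  feats <- feats[c(front, setdiff(names(feats), front))]
  if (standardize) feats <- log_standardize(feats, columns = feature_cols)
  if (verbose) {
    nf <- sum(feats$flag != "")
    message(sprintf("processed %d documents (%d flagged: %s); dropped chunks: %d",
                    nrow(feats), nf,
                    if (nf) paste(unique(feats$flag[feats$flag != ""]),
                                  collapse = ",") else "none",
                    sum(feats$dropped_chunks)))
  }
  attr(feats, "config") <- config
  feats
}

#' Log-transform and corpus-standardize feature columns
#'
#' For each selected column adds `log_<col>` (natural log) and `z_log_<col>`,
#' the z-score of the log over non-flagged rows (sample standard deviation,
#' denominator n-1). The feature distributions are right-skewed, so models
#' downstream use these transformed columns. A zero-variance column yields
#' zeros with a warning; a nonpositive value in a non-flagged row is an
#' internal error (degenerate rows must be flagged upstream).
#'
#' @param table per-document feature data.frame with a `flag` column.
#' @param columns character vector of column names to transform.
#' @return the table with added columns; flagged rows carry `NA`.
#' @export
log_standardize <- function(table, columns = feature_cols) {
  ok <- table$flag == ""
  for (col in columns) {
    x <- table[[col]]
    if (any(ok & (!is.finite(x) | x <= 0))) {
      stop(sprintf("internal error: nonpositive '%s' in a non-flagged row", col),
           call. = FALSE)
    }
    lg <- ifelse(ok, log(x), NA_real_)
    z <- rep(NA_real_, length(x))
    if (sum(ok) >= 2L) {
      s <- sd(lg[ok])
      if (is.na(s) || s == 0) {
        warning(sprintf("column '%s' has zero variance on the log scale; z set to 0",
                        col), call. = FALSE)
        z[ok] <- 0
      } else {
        z[ok] <- (lg[ok] - mean(lg[ok])) / s
      }
    } else if (sum(ok) == 1L) {
      z[ok] <- 0
    }
    table[[paste0("log_", col)]] <- lg
    table[[paste0("z_log_", col)]] <- z
  }
  table
}

#' Aggregate a per-document feature table to authors
#'
#' Averages each author's standardized (and log) feature columns over their
#' non-flagged documents -- each author contributes one row of analysis, as
#' when a student writes two essays and the analysis unit is the student.
#' With `config$aggregate = "z_of_mean"` the per-author mean of the log
#' features is standardized across authors instead. Numeric covariates are
#' averaged over the author's documents; other covariates take the author's
#' first value. Authors with no valid document are kept, flagged.
#'
#' @param table per-document table from [process_corpus()].
#' @param config a [topo_config()]; only the `aggregate` field is used.
#' @return data.frame with one row per author (`author_id`, `n_docs`,
#'   feature aggregates, covariates, `flag`).
#' @export
aggregate_by_author <- function(table, config = attr(table, "config") %||% topo_config()) {
  stopifnot("author_id" %in% names(table))
  f <- factor(table$author_id, levels = unique(table$author_id))
  authors <- levels(f)
  zcols <- grep("^z_log_", names(table), value = TRUE)
  lcols <- grep("^log_", names(table), value = TRUE)
  covar <- setdiff(names(table),
                   c("doc_id", "author_id", "T", "d", "speed", "raw_volume",
                     "norm_volume", "min_required_speed", "circuitousness",
                     "solver", "dropped_chunks", "flag", zcols, lcols))
  ok <- table$flag == ""
  n_ok <- as.vector(table(f[ok])[authors])
  n_ok[is.na(n_ok)] <- 0L
  group_mean <- function(x) {
    s <- rep(NA_real_, length(authors))
    if (any(ok)) {
      sums <- rowsum(x[ok], f[ok])
      s[match(rownames(sums), authors)] <- sums[, 1] / n_ok[match(rownames(sums), authors)]
    }
    s
  }
  out <- data.frame(author_id = authors, n_docs = n_ok,
                    stringsAsFactors = FALSE)
  for (col in c(lcols, zcols)) out[[col]] <- group_mean(table[[col]])
  out$T <- group_mean(as.numeric(table$T))
  first_idx <- match(authors, table$author_id)
  for (cv in covar) {
    v <- table[[cv]]
    out[[cv]] <- if (is.numeric(v)) {
      sums <- rowsum(v, f)
      as.vector(sums[match(authors, rownames(sums)), 1]) /
        as.vector(table(f)[authors])
    } else {
      v[first_idx]
    }
  }
  out$flag <- ifelse(n_ok > 0L, "", "no_valid_documents")
  if (config$aggregate == "z_of_mean") {
    ok <- out$flag == ""
    for (col in zcols) {
      base <- out[[sub("^z_", "", col)]]  # the author-mean log column
      if (sum(ok) >= 2L) {
        s <- sd(base[ok])
        out[[col]][ok] <- if (is.na(s) || s == 0) 0 else
          (base[ok] - mean(base[ok])) / s
      }
    }
  }
  attr(out, "config") <- config
  out
}

#' Write a feature table with a reproducibility header
#'
#' Tab-separated UTF-8 with every configuration value serialized in
#' `#key=value` header lines and numerics written with 17 significant
#' digits, so the file round-trips to the exact doubles and two identical
#' runs produce byte-identical files.
#'
#' @param table feature data.frame (with attribute `"config"`).
#' @param path output path.
#' @param config configuration to serialize (defaults to the table's).
#' @export
write_feature_table <- function(table, path,
                                config = attr(table, "config") %||% topo_config()) {
  hdr <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("#%s=%s", k, if (is.null(v)) "" else as.character(v))
  }, character(1))
  out <- table
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(c(paste0("#schema=1"), hdr), con)
  close(con)
  suppressWarnings(data.table::fwrite(out, path, sep = "\t", append = TRUE,
                                      col.names = TRUE, quote = "auto"))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path file path.
#' @return data.frame; header key-values are attached as attribute `"header"`.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  nh <- which(!startsWith(lines, "#"))[1] - 1L
  hdr <- strsplit(sub("^#", "", lines[seq_len(nh)]), "=", fixed = TRUE)
  header <- setNames(vapply(hdr, function(p) paste(p[-1], collapse = "="),
                            character(1)),
                     vapply(hdr, `[`, character(1), 1L))
  df <- data.table::setDF(data.table::fread(path, sep = "\t", skip = nh,
                                            header = TRUE, data.table = FALSE,
                                            na.strings = "NA"))
  attr(df, "header") <- header
  df
}
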