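#' Deterministic hash-based embedding store
#'
#' Maps every word to a pseudo-random unit vector derived only from the word
#' string and a seed (31-ary string hash feeding a locally seeded normal
#' draw), so the same `(word, seed)` pair yields the same vector on any
#' platform and no pretrained vectors are ever needed for testing.
#'
#' @param vocabulary character vector of words.
#' @param d embedding dimension (default 300).
#' @param seed integer seed.
#' @return an [embedding_store()].
#' @export
hash_embedding_store <- function(vocabulary, d = 300L, seed = 1L) {
  stopifnot(d >= 1L, !anyDuplicated(vocabulary))
  vec <- t(vapply(vocabulary, function(w) {
    v <- with_seed(string_seed(w, seed), rnorm(d))
    v / sqrt(sum(v^2))
  }, numeric(d)))
  rownames(vec) <- vocabulary
  embedding_store(vec)
}

#' Generate a path with planted spread, step size, and ordering
#'
#' Builds a smooth serpentine curve in a random 2-plane of the ambient
#' space: one coordinate sweeps linearly across the target spread `scale`
#' while the other oscillates with amplitude `scale / 2`, the oscillation
#' frequency chosen so the mean consecutive step is approximately `step`.
#' The curve is then rescaled so the dim-root volume of its enclosing
#' ellipse is exactly proportional to `scale`: `scale` is the planted
#' volume by construction, while `step` is honored approximately.
#' When the requested step budget `step * (T - 1)` cannot exceed `scale`,
#' the curve degenerates to a straight line with exact step `step` (and
#' spread below `scale`). In `"sorted"` mode the points are returned in
#' curve order, which is (near-)optimal, so circuitousness is close to 1; in
#' `"shuffled"` mode the same point set is returned with the interior
#' randomly permuted and the endpoints kept, which raises speed and
#' circuitousness while leaving volume and minimum required speed unchanged.
#'
#' @param T number of points (>= 3).
#' @param d ambient dimension (>= 2).
#' @param scale target overall spread of the point set.
#' @param step target consecutive step size.
#' @param order_mode `"sorted"` or `"shuffled"`.
#' @param seed integer seed.
#' @return a [semantic_path()].
#' @export
generate_planted_path <- function(T = 22L, d = 10L, scale = 12, step = 1,
                                  order_mode = c("sorted", "shuffled"),
                                  seed = 1L) {
  order_mode <- match.arg(order_mode)
  stopifnot(T >= 3L, d >= 2L, scale > 0, step > 0)
  with_seed(seed, {
    tau <- seq(0, 1, length.out = T)
    L <- step * (T - 1)
    if (L <= scale) {
      uv <- cbind(L * tau, 0)
    } else {
      Phi <- 2 * sqrt(2) * sqrt((L / scale)^2 - 1)
      phi0 <- runif(1, 0, 2 * pi)
      uv <- cbind(scale * tau, (scale / 2) * sin(Phi * tau + phi0))
      # normalize so the enclosing-ellipse dim-root volume is exactly
      # proportional to scale: `scale` is the planted volume, by construction
      v0 <- normalized_volume(mvee(project_coords(uv)$coords), T, "dim_root")
      uv <- uv * (scale / v0)
    }
    basis <- qr.Q(qr(matrix(rnorm(d * 2L), d, 2L)))
    pts <- uv %*% t(basis)
    if (order_mode == "shuffled" && T > 3L) {
      perm <- c(1L, 1L + sample(T - 2L), T)
      pts <- pts[perm, , drop = FALSE]
    }
    semantic_path(pts)
  })
}

#' Generate a synthetic corpus with planted volume and speed effects
#'
#' Emulates a study in which each author writes `docs_per_author` documents
#' of about `tokens_per_doc` words and an author-level outcome depends
#' linearly on the standardized log volume and log speed of their writing.
#' Text is synthesized over an artificial vocabulary (`w0001`, `w0002`, ...)
#' against a [hash_embedding_store()], so tokenization is trivially exact
#' and no language resource is needed. Three per-document knobs create
#' feature variation: the number of distinct topic words, the width of the
#' sliding topic window that words are drawn from (narrow windows make
#' consecutive chunks share vocabulary, lowering speed while the chunk
#' means spread out), and a partial shuffle of chunk-sized blocks (raising
#' speed and circuitousness at fixed content). The outcome is
#' `beta_volume * z(log volume) + beta_speed * z(log speed) + noise` at the
#' author level, computed from the same feature pipeline the package
#' applies to real corpora.
#'
#' @param n_authors number of authors.
#' @param docs_per_author documents per author (default 2).
#' @param tokens_per_doc words per document (default 550).
#' @param beta_volume,beta_speed planted standardized effects.
#' @param noise_sd standard deviation of the outcome noise.
#' @param seed integer seed.
#' @param vocab_size size of the artificial vocabulary.
#' @param dim embedding dimension of the hash store.
#' @param config a [topo_config()] used to measure the planted features.
#' @return list with `corpus` (doc_id, author_id, text, outcome), `truth`
#'   (per-author standardized features and outcome), `doc_features`
#'   (per-document feature table), and `store`.
#' @export
generate_corpus <- function(n_authors, docs_per_author = 2L,
                            tokens_per_doc = 550L,
                            beta_volume = 0.15, beta_speed = -0.05,
                            noise_sd = 1, seed = 1L,
                            vocab_size = 2000L, dim = 300L,
                            config = topo_config()) {
  stopifnot(n_authors >= 1L, docs_per_author >= 1L, tokens_per_doc >= 1L,
            noise_sd >= 0)
  vocab <- sprintf("w%05d", seq_len(vocab_size))
  store <- hash_embedding_store(vocab, d = dim, seed = seed)
  n_docs <- n_authors * docs_per_author
  author_id <- rep(sprintf("a%05d", seq_len(n_authors)),
                   each = docs_per_author)
  doc_id <- sprintf("%s_d%d", author_id,
                    rep(seq_len(docs_per_author), times = n_authors))
  cs <- config$chunk_size
  token_list <- with_seed(seed + 1L, lapply(seq_len(n_docs), function(i) {
    m <- round(exp(runif(1, log(40), log(220))))
    w <- exp(runif(1, log(0.10), log(0.35))) # window width, fraction of m
    sfrac <- runif(1, 0, 1)                  # shuffled fraction of blocks
    topics <- sample.int(vocab_size, m)
    centers <- seq(1, m, length.out = tokens_per_doc)
    pos <- round(centers + rnorm(tokens_per_doc) * w * m)
    pos <- (pos - 1L) %% (2L * m)           # reflect into 1..m
    pos <- ifelse(pos >= m, 2L * m - 1L - pos, pos) + 1L
    words <- vocab[topics[pos]]
    nb <- ceiling(tokens_per_doc / cs)
    if (nb > 3L && sfrac > 0) {
      k <- round(sfrac * (nb - 2L))
      if (k >= 2L) {
        sel <- sort(sample(2:(nb - 1L), k))
        ids <- seq_len(nb)
        ids[sel] <- sample(sel)
        block <- rep(seq_len(nb), each = cs, length.out = tokens_per_doc)
        words <- unlist(split(words, block)[as.character(ids)],
                        use.names = FALSE)
      }
    }
    words
  }))
  feats <- features_for_tokens(token_list, doc_id, store, config)
  feats$author_id <- author_id
  degen <- feats$flag == "" &
    (!is.finite(feats$speed) | feats$speed <= 0 |
       !is.finite(feats$norm_volume) | feats$norm_volume <= 0)
  feats$flag[degen] <- "degenerate"
  feats <- log_standardize(feats, columns = feature_cols)
  truth <- aggregate_by_author(feats, config)
  # plant effects on unit-variance author-level features -- the same scale
  # the standardized association fit estimates on, so recovery is calibrated
  rez <- function(x) {
    ok <- is.finite(x)
    z <- rep(NA_real_, length(x))
    z[ok] <- (x[ok] - mean(x[ok])) / sd(x[ok])
    z
  }
  outcome <- with_seed(seed + 2L,
                       beta_volume * rez(truth$z_log_norm_volume) +
                         beta_speed * rez(truth$z_log_speed) +
                         rnorm(nrow(truth), 0, noise_sd))
  truth$outcome <- outcome
  corpus <- data.frame(
    doc_id = doc_id, author_id = author_id,
    text = vapply(token_list, paste, character(1), collapse = " "),
    outcome = truth$outcome[match(author_id, truth$author_id)],
    stringsAsFactors = FALSE)
  list(corpus = corpus, truth = truth, doc_features = feats, store = store)
}

#' Brute-force shortest fixed-endpoint path
#'
#' Exhaustively enumerates all `(T - 2)!` interior orders (in lexicographic
#' order, so ties resolve to the lexicographically smallest optimum) and
#' returns the global minimum. Only feasible for T <= 9; intended as an
#' independent oracle for the dynamic-programming and heuristic solvers.
#'
#' @param points a `semantic_path` or T x D point matrix, 2 <= T <= 9.
#' @return a `path_solution` with solver `"exact"` (`"trivial"` for T = 2).
#' @export
brute_force_min_path <- function(points) {
  X <- as_point_matrix(points)
  T <- nrow(X)
  if (T < 2L) stop("path too short: need at least 2 points", call. = FALSE)
  if (T > 9L) stop("brute force refused for T > 9", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  if (T == 2L) {
    return(structure(list(order = c(1L, 2L), total_length = D[1, 2],
                          solver = "trivial"), class = "path_solution"))
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_len <- Inf
  for (p in perms(seq(2L, T - 1L))) {
    ord <- c(1L, p, T)
    len <- sum(D[cbind(ord[-T], ord[-1L])])
    if (len < best_len) {  # strict: first (lexicographic) optimum wins ties
      best_len <- len
      best <- ord
    }
  }
  structure(list(order = best, total_length = best_len, solver = "exact"),
            class = "path_solution")
}

#' Verify the optimality conditions of an enclosing ellipsoid
#'
#' Checks John's conditions for a minimum-volume enclosing ellipsoid:
#' every point is contained (`(x - c)' A (x - c) <= 1 + tol`), some points
#' lie on the boundary, and nonnegative weights supported on those boundary
#' points reproduce the center and the shape matrix
#' (`sum u_i (x_i - c)(x_i - c)' = A^{-1} / d`, `sum u_i = 1`). The weights
#' are recovered by least squares from the linear system the conditions
#' define; a shrunken ellipsoid fails containment, an inflated one has no
#' boundary support.
#'
#' @param points numeric T x d matrix (full rank).
#' @param ell a `topo_ellipsoid` for those points.
#' @param tol tolerance for all three checks (default 1e-3).
#' @return list report: `pass`, `containment_ok`, `support_ok`,
#'   `weights_ok`, `max_maha`, `n_support`, `residual`.
#' @export
verify_mvee_optimality <- function(points, ell, tol = 1e-3) {
  X <- as_point_matrix(points)
  d <- ell$d
  stopifnot(ncol(X) == d, d >= 1L)
  C <- sweep(X, 2L, ell$center)
  maha <- rowSums((C %*% ell$shape) * C)
  containment_ok <- max(maha) <= 1 + tol
  support <- which(maha >= 1 - tol)
  support_ok <- length(support) >= d + 1L
  weights_ok <- FALSE
  residual <- NA_real_
  if (support_ok) {
    Xs <- X[support, , drop = FALSE]
    Cs <- C[support, , drop = FALSE]
    Sigma_target <- solve(ell$shape) / d
    iu <- which(upper.tri(Sigma_target, diag = TRUE))
    # rows: center (d), total mass (1), scatter entries (d(d+1)/2)
    A_ls <- rbind(t(Xs), rep(1, length(support)),
                  apply(Cs, 1L, function(r) tcrossprod(r)[iu]))
    b_ls <- c(ell$center, 1, Sigma_target[iu])
    u <- qr.solve(qr(A_ls, LAPACK = TRUE), b_ls)
    residual <- sqrt(sum((A_ls %*% u - b_ls)^2)) / sqrt(sum(b_ls^2))
    weights_ok <- residual <= tol && min(u) >= -tol &&
      abs(sum(u) - 1) <= tol
  }
  list(pass = containment_ok && support_ok && weights_ok,
       containment_ok = containment_ok, support_ok = support_ok,
       weights_ok = weights_ok, max_maha = max(maha),
       n_support = length(support), residual = residual)
}
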