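# Shared fixtures and independent oracles, all generated in code.

# Random point cloud / path fixture.
rand_points <- function(T, d, seed, sd = 1) {
  set.seed(seed)
  matrix(rnorm(T * d, sd = sd), T, d)
}

# High-precision MVEE oracle: same dual ascent run to a far tighter duality
# gap, accepted only if John's optimality conditions verify independently.
oracle_mvee <- function(points) {
  ell <- mvee(points, tol = 1e-12, max_iter = 500000L)
  rep <- verify_mvee_optimality(points, ell, tol = 1e-3)
  stopifnot(rep$pass)
  ell
}

# Small hand-built embedding store.
toy_store <- function() {
  vec <- rbind(a = c(0, 2, 0), b = c(2, 0, 0), c = c(0, 0, 2), d = c(1, 1, 1))
  embedding_store(vec)
}

# Random rotation matrix (Haar via QR with positive diagonal correction).
rand_rotation <- function(d, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), d)
}

# Observed path length of the identity order.
observed_length <- function(X) sum(consecutive_distances(X))

# A tiny deterministic corpus built from the hash-store vocabulary.
toy_corpus <- function(n_docs = 4, tokens = 120, vocab_size = 300, seed = 5) {
  vocab <- sprintf("w%05d", seq_len(vocab_size))
  store <- hash_embedding_store(vocab, d = 20, seed = seed)
  set.seed(seed + 1)
  corpus <- data.frame(
    doc_id = sprintf("doc%02d", seq_len(n_docs)),
    author_id = sprintf("auth%02d", rep(seq_len(ceiling(n_docs / 2)),
                                        each = 2, length.out = n_docs)),
    text = vapply(seq_len(n_docs), function(i) {
      paste(sample(vocab, tokens, replace = TRUE), collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE)
  list(corpus = corpus, store = store)
}
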