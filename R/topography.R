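#' Euclidean distances between consecutive path points
#'
#' @param path a `semantic_path` or T x D point matrix with T >= 2.
#' @return numeric vector of length T-1; element t is `||x_{t+1} - x_t||`.
#' @export
consecutive_distances <- function(path) {
  X <- as_point_matrix(path)
  if (nrow(X) < 2L) stop("path too short: need at least 2 points", call. = FALSE)
  sqrt(rowSums((X[-1L, , drop = FALSE] - X[-nrow(X), , drop = FALSE])^2))
}

#' Semantic speed of a path
#'
#' The mean Euclidean distance between consecutive points, i.e. the total
#' distance travelled divided by T-1. Larger values mean bigger jumps
#' between adjacent chunks of content.
#'
#' @inheritParams consecutive_distances
#' @return nonnegative scalar.
#' @export
path_speed <- function(path) {
  mean(consecutive_distances(path))
}

#' Project points onto an orthonormal basis of their affine hull
#'
#' A handful of points in a high-dimensional embedding space (say T ~ 22
#' points in 300 dimensions) span an affine subspace of dimension at most
#' T-1, so any full-dimensional enclosing ellipsoid is degenerate with
#' volume zero. All ellipsoid computations are therefore carried out in the
#' affine hull: points are centered and re-expressed in an orthonormal basis
#' obtained from the singular value decomposition, keeping singular values
#' above `rank_tol` times the largest. Pairwise distances are preserved
#' exactly (up to floating point), so speed and path-length quantities are
#' unaffected by the projection.
#'
#' @param points numeric T x D matrix (at least one point).
#' @param rank_tol relative singular-value cutoff for the numerical rank.
#' @return list with `coords` (T x d matrix), `d` (effective dimension),
#'   `basis` (D x d), `centroid` (length-D).
#' @export
project_to_affine_subspace <- function(points, rank_tol = 1e-9) {
  X <- as_point_matrix(points)
  stopifnot(nrow(X) >= 1L)
  centroid <- colMeans(X)
  C <- sweep(X, 2L, centroid)
  if (nrow(X) == 1L || max(abs(C)) == 0) {
    return(list(coords = matrix(0, nrow(X), 0L), d = 0L,
                basis = matrix(0, ncol(X), 0L), centroid = centroid))
  }
  sv <- svd(C)
  d <- sum(sv$d > rank_tol * sv$d[1])
  coords <- sv$u[, seq_len(d), drop = FALSE] %*%
    diag(sv$d[seq_len(d)], nrow = d)
  list(coords = coords, d = as.integer(d),
       basis = sv$v[, seq_len(d), drop = FALSE], centroid = centroid)
}

# Fast internal variant: affine-hull coordinates without the basis (the
# right singular vectors are never formed), for the corpus hot path.
project_coords <- function(X, rank_tol = 1e-9) {
  C <- sweep(X, 2L, colMeans(X))
  if (nrow(X) == 1L || max(abs(C)) == 0) {
    return(list(coords = matrix(0, nrow(X), 0L), d = 0L))
  }
  sv <- svd(C, nu = min(dim(C)), nv = 0)
  d <- sum(sv$d > rank_tol * sv$d[1])
  coords <- sv$u[, seq_len(d), drop = FALSE] %*%
    diag(sv$d[seq_len(d)], nrow = d)
  list(coords = coords, d = as.integer(d))
}

#' Minimum-volume enclosing ellipsoid (Khachiyan algorithm)
#'
#' Computes the Loewner-John ellipsoid of a full-rank point set by the
#' Khachiyan multiplicative weight-update scheme on the dual (D-optimal
#' design) formulation, accelerated with Wolfe-Atwood away steps. Iterations
#' stop once the maximum lifted Mahalanobis value is within `(1 + tol)` of
#' its optimal value `d + 1`. The returned shape matrix is scaled by the
#' measured maximum Mahalanobis value so that `(x - c)' A (x - c) <= 1`
#' holds exactly for every input point; the resulting volume overshoots the
#' true optimum by at most a factor `(1 + tol)^(d/2)`.
#'
#' @param points numeric T x d matrix of full column rank (project first with
#'   [project_to_affine_subspace()]); requires `T >= d + 1`.
#' @param tol convergence tolerance on the relative duality violation.
#' @param max_iter maximum number of weight updates.
#' @return object of class `topo_ellipsoid`: `center` (length d), `shape`
#'   (d x d positive-definite matrix `A`), `volume` (d-dimensional Lebesgue
#'   measure), `d`, `support_weights`, `iterations`, `kappa`.
#' @examples
#' e <- mvee(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
#' e$volume  # pi/2: the disk circumscribing the unit square
#' @export
mvee <- function(points, tol = 1e-7, max_iter = 50000L) {
  X <- as_point_matrix(points)
  d <- ncol(X)
  T <- nrow(X)
  if (d == 0L) {
    return(structure(list(center = numeric(0),
                          shape = matrix(numeric(0), 0, 0),
                          volume = 0, d = 0L, support_weights = rep(1 / T, T),
                          iterations = 0L, kappa = 0, log_volume = -Inf),
                     class = "topo_ellipsoid"))
  }
  if (T < d + 1L) {
    stop(sprintf("need at least d + 1 = %d points for a full-rank %d-dimensional ellipsoid (got %d)",
                 d + 1L, d, T), call. = FALSE)
  }
  res <- cpp_mvee(X, tol, as.integer(max_iter))
  if (!res$converged) {
    stop(sprintf("MVEE did not converge in %d iterations (d = %d, T = %d, kappa = %.10g, tol = %g)",
                 res$iterations, d, T, res$kappa, tol), call. = FALSE)
  }
  log_volume <- log(unit_ball_volume(d)) + res$log_sqrt_det
  structure(list(center = as.numeric(res$center), shape = res$shape,
                 volume = exp(log_volume), d = as.integer(d),
                 support_weights = as.numeric(res$u),
                 iterations = res$iterations, kappa = res$kappa,
                 log_volume = log_volume),
            class = "topo_ellipsoid")
}

#' @export
print.topo_ellipsoid <- function(x, ...) {
  cat(sprintf("<topo_ellipsoid: d = %d, volume = %.6g (%d iterations)>\n",
              x$d, x$volume, x$iterations))
  invisible(x)
}

#' Length-normalized semantic volume
#'
#' Raw ellipsoid volume is a d-dimensional measure and not comparable across
#' documents whose affine hulls have different dimensions, so by default the
#' per-dimension length scale `volume^(1/d)` is reported (`dim_root`).
#' `per_chunk` further divides by the number of points T; `raw` returns the
#' Lebesgue volume unchanged. T and d are always carried alongside in the
#' feature table so downstream models can control for document length.
#'
#' @param ell a `topo_ellipsoid`.
#' @param T number of path points.
#' @param mode `"dim_root"` (default), `"per_chunk"`, or `"raw"`.
#' @return nonnegative scalar (0 for a degenerate, zero-dimensional hull).
#' @export
normalized_volume <- function(ell, T, mode = c("dim_root", "per_chunk", "raw")) {
  mode <- match.arg(mode)
  if (ell$d == 0L) return(0)
  switch(mode,
         raw = ell$volume,
         dim_root = exp(ell$log_volume / ell$d),
         per_chunk = exp(ell$log_volume / ell$d) / T)
}

#' Exact shortest fixed-endpoint path (Held-Karp)
#'
#' Finds the globally shortest Hamiltonian path through all points with the
#' first and last point fixed, by dynamic programming over subsets of the
#' interior points. Ties are broken toward the lexicographically smallest
#' visiting order so results are reproducible. Complexity is
#' O(2^m m^2) for m = T - 2 interior points; calls with `m > exact_max` are
#' refused and should use [min_path_heuristic()].
#'
#' @param path a `semantic_path` or T x D point matrix, T >= 2.
#' @param exact_max largest interior-point count accepted (default 12).
#' @return object of class `path_solution`: `order` (permutation of 1..T with
#'   fixed ends), `total_length`, `solver` (`"exact"`, or `"trivial"` for
#'   T = 2).
#' @export
min_path_exact <- function(path, exact_max = 12L) {
  X <- as_point_matrix(path)
  T <- nrow(X)
  if (T < 2L) stop("path too short: need at least 2 points", call. = FALSE)
  if (T - 2L > exact_max) {
    stop(sprintf("%d interior points exceed exact_max = %d; use min_path_heuristic()",
                 T - 2L, exact_max), call. = FALSE)
  }
  res <- cpp_held_karp(X)
  structure(list(order = as.integer(res$order),
                 total_length = res$total_length,
                 solver = if (T == 2L) "trivial" else "exact"),
            class = "path_solution")
}

#' Heuristic shortest fixed-endpoint path (2-opt with restarts)
#'
#' Polishes each of {the observed order, a nearest-neighbour construction
#' from the start, `restarts` seeded random interior orders} with 2-opt
#' until no improving segment reversal remains, and returns the best.
#' Because the observed order is always a candidate and 2-opt never makes a
#' path longer, the result never exceeds the observed path length -- so
#' circuitousness computed from it is always >= 1. Deterministic for a fixed
#' seed.
#'
#' @param path a `semantic_path` or point matrix, T >= 2.
#' @param restarts number of random restarts (default 10).
#' @param seed integer seed for the restart shuffles.
#' @return a `path_solution` with solver `"heuristic"` (`"trivial"` for T = 2).
#' @export
min_path_heuristic <- function(path, restarts = 10L, seed = 42L) {
  X <- as_point_matrix(path)
  T <- nrow(X)
  if (T < 2L) stop("path too short: need at least 2 points", call. = FALSE)
  res <- cpp_min_path_heuristic(X, as.integer(restarts), as.integer(seed))
  structure(list(order = as.integer(res$order),
                 total_length = res$total_length,
                 solver = if (T == 2L) "trivial" else "heuristic"),
            class = "path_solution")
}

#' @export
print.path_solution <- function(x, ...) {
  cat(sprintf("<path_solution (%s): length %.6g, order %s>\n",
              x$solver, x$total_length,
              paste(head(x$order, 12L), collapse = " ")))
  invisible(x)
}

#' Minimum required speed
#'
#' The speed the document would have had if its points were visited in the
#' shortest admissible order: the optimal path length divided by T - 1.
#'
#' @param sol a `path_solution`.
#' @param T number of path points.
#' @return nonnegative scalar.
#' @export
min_required_speed <- function(sol, T) {
  stopifnot(T >= 2L)
  sol$total_length / (T - 1)
}

#' Circuitousness of a path
#'
#' Observed speed divided by minimum required speed: how suboptimally the
#' content is ordered given what it covers. Equals 1 when the observed order
#' is already optimal; with an exact solver it is always >= 1. When all
#' points coincide both speeds are 0 and the ratio is defined as 1 with a
#' `"degenerate"` attribute; a zero minimum with nonzero observed speed is
#' impossible for a valid path and raises an error.
#'
#' @param speed_value observed speed of the path.
#' @param min_speed minimum required speed of the same path.
#' @return scalar ratio, possibly with attribute `degenerate = TRUE`.
#' @export
circuitousness <- function(speed_value, min_speed) {
  if (min_speed == 0) {
    if (speed_value > 0) {
      stop("internal inconsistency: zero minimum required speed with positive observed speed",
           call. = FALSE)
    }
    return(structure(1, degenerate = TRUE))
  }
  speed_value / min_speed
}

#' Extract all topography features from one semantic path
#'
#' Computes speed, ellipsoid volume in the affine hull, minimum required
#' speed (exact Held-Karp when the interior-point count is within
#' `config$exact_max`, otherwise the 2-opt heuristic), and circuitousness.
#' The identity `log(speed) = log(circuitousness) + log(min_required_speed)`
#' holds by construction. Paths flagged too short get `NA` features and the
#' reason in `flags`.
#'
#' @param path a `semantic_path`.
#' @param config a [topo_config()].
#' @return object of class `topo_features`; see [as.data.frame.topo_features()].
#' @export
extract_features <- function(path, config = topo_config()) {
  stopifnot(inherits(path, "semantic_path"))
  base <- list(doc_id = path$doc_id, T = path$T, d = NA_integer_,
               speed = NA_real_, raw_volume = NA_real_, norm_volume = NA_real_,
               min_required_speed = NA_real_, circuitousness = NA_real_,
               solver = NA_character_, dropped_chunks = path$dropped_chunks,
               flags = path$flags)
  if (path$T < 2L) {
    return(structure(base, class = "topo_features"))
  }
  sp <- path_speed(path)
  proj <- project_coords(path$points, rank_tol = config$rank_tol)
  ell <- mvee(proj$coords, tol = config$mvee_tol,
              max_iter = config$mvee_max_iter)
  sol <- if (path$T - 2L <= config$exact_max) {
    min_path_exact(path, exact_max = config$exact_max)
  } else {
    min_path_heuristic(path, restarts = config$restarts, seed = config$seed)
  }
  msp <- min_required_speed(sol, path$T)
  circ <- circuitousness(sp, msp)
  flags <- path$flags
  if (isTRUE(attr(circ, "degenerate"))) flags <- c(flags, "degenerate")
  out <- modifyList(base, list(
    d = proj$d, speed = sp, raw_volume = ell$volume,
    norm_volume = normalized_volume(ell, path$T, mode = config$volume_mode),
    min_required_speed = msp, circuitousness = as.numeric(circ),
    solver = sol$solver, flags = flags))
  structure(out, class = "topo_features")
}

#' @export
print.topo_features <- function(x, ...) {
  cat(sprintf(
    "<topo_features%s: T = %d, d = %s, speed = %.5g, volume = %.5g, min speed = %.5g, circuitousness = %.5g (%s)%s>\n",
    if (is.null(x$doc_id)) "" else paste0(" ", x$doc_id),
    x$T, format(x$d), x$speed, x$norm_volume, x$min_required_speed,
    x$circuitousness, x$solver %||% "none",
    if (length(x$flags)) paste0("; flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @describeIn extract_features one-row data.frame of the feature fields.
#' @param x a `topo_features` object.
#' @param ... unused.
#' @export
as.data.frame.topo_features <- function(x, ...) {
  data.frame(doc_id = x$doc_id %||% NA_character_, T = x$T, d = x$d,
             speed = x$speed, raw_volume = x$raw_volume,
             norm_volume = x$norm_volume,
             min_required_speed = x$min_required_speed,
             circuitousness = x$circuitousness,
             solver = x$solver, dropped_chunks = x$dropped_chunks,
             flag = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
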