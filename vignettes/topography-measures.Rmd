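---
title: "Measuring the topography of written thought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the topography of written thought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

topothought treats a document as a trajectory through semantic space and
asks three questions about it: how much ground does it cover, how fast does
it move, and how efficiently is it ordered? This vignette describes the
model behind those measures, the tunable parameters and their defaults, the
synthetic-data machinery used to test everything, and the numerical choices
and known limitations.

## The trajectory model

A document is tokenized, split into consecutive chunks of `chunk_size`
tokens (default 25), and each chunk is embedded as the unweighted mean of
its in-vocabulary word vectors. The result is an ordered path
$\{x_1, \dots, x_T\}$ in the embedding space (conventionally 300
dimensions). Four quantities describe the path:

* **Speed** — the mean Euclidean distance between consecutive points,
  $\frac{1}{T-1}\sum_{t=1}^{T-1} \lVert x_{t+1} - x_t \rVert$. Large values
  mean adjacent passages are semantically far apart.
* **Volume** — the volume of the minimum-volume enclosing ellipsoid
  (Löwner–John ellipsoid) of the $T$ points: how much semantic ground the
  document covers, regardless of order.
* **Minimum required speed** — the length of the shortest path that starts
  at $x_1$, ends at $x_T$, and visits every other point (an open
  traveling-salesperson optimum with fixed endpoints), divided by $T-1$.
  This is the speed the document *would* have needed given the content it
  chose.
* **Circuitousness** — observed speed divided by minimum required speed.
  It isolates ordering: a value of 1 means the content was presented in an
  optimal sequence; larger values mean the same content was traversed
  inefficiently. By construction
  $\log(\text{speed}) = \log(\text{circuitousness}) +
  \log(\text{min required speed})$, so on the log scale speed decomposes
  exactly into a selection part and an ordering part.

```{r}
library(topothought)
path <- generate_planted_path(T = 12, d = 6, scale = 8, step = 1, seed = 3)
extract_features(path)
```

## Why the ellipsoid lives in the affine hull

A typical document yields roughly 20–25 chunk points, while the embedding
space has hundreds of dimensions. Any ellipsoid around $T$ points in more
than $T-1$ dimensions is degenerate with zero volume, so the package first
projects the points onto an orthonormal basis of their affine hull
(dimension $d \le T-1$, found by singular value decomposition with a
relative cutoff `rank_tol = 1e-9`) and computes the ellipsoid there.
Pairwise distances are unchanged by the projection, so speed and path
lengths are unaffected. The effective dimension $d$ is reported in every
feature table: documents of different lengths live in hulls of different
dimension, and downstream models can control for it.

Raw $d$-dimensional volumes are not comparable across documents with
different $d$ (their units differ), so the default reported volume is the
per-dimension length scale $\text{volume}^{1/d}$ (`volume_mode =
"dim_root"`). This is a declared normalization choice, not an estimate of
anyone else's: the alternatives (`"per_chunk"`, which further divides by
$T$, and `"raw"`) are one flag away, and $T$ and $d$ always travel with
the features so document length can be controlled for explicitly in the
regression stage, which is what the association models here do.

## Solving the two optimization problems

**Ellipsoid.** The minimum-volume enclosing ellipsoid is computed by the
Khachiyan multiplicative weight-update scheme on the dual D-optimal design
formulation, with Wolfe–Atwood away steps for faster convergence.
Iteration stops when the largest lifted Mahalanobis value is within a
factor $1 + \texttt{mvee\_tol}$ (default $10^{-7}$) of its optimal value.
Rather than inflating the shape matrix by the fixed factor
$(1+\text{tol})$, the returned shape is scaled by the *measured* maximum
Mahalanobis value, so containment of every input point holds exactly (up
to floating point) and already-converged cases — such as two points in one
dimension, whose enclosing "ellipsoid" is the spanning interval — come out
exact rather than inflated. The volume overshoot is bounded by
$(1+\text{tol})^{d/2}$ either way. Tests verify the result against a
tight-tolerance run combined with an independent check of John's
optimality conditions (containment, boundary support, and nonnegative
support weights reproducing the center and scatter), and against the
independent Titterington implementation in `cluster::ellipsoidhull`.

**Shortest path.** With endpoints fixed, documents with at most
`exact_max = 12` interior points are solved exactly by Held–Karp dynamic
programming over interior subsets ($O(2^m m^2)$, well under a second at
$m = 12$), with ties broken toward the lexicographically smallest order so
results are reproducible. Longer documents — a 550-word essay yields
$T \approx 22$, i.e. 20 interior points — use a heuristic: the best of the
observed order, a nearest-neighbour construction, and `restarts = 10`
seeded random orders, each polished by 2-opt segment reversals until no
improvement remains. Because the observed order is always a candidate,
the heuristic never exceeds the observed path length and circuitousness is
always at least 1, with either solver. The solver used is recorded per
document in the `solver` column.

## From documents to an analysis table

`process_corpus()` computes features per document, flags degenerate rows
(empty documents, single-chunk documents, paths with zero speed or volume)
instead of dropping them, then log-transforms the four features (their
distributions are right-skewed) and z-scores the logs across non-flagged
documents (sample standard deviation, $n-1$). `aggregate_by_author()`
averages each author's standardized document features over their valid
documents, mirroring a design where each student writes two essays and the
student is the unit of analysis. Averaging the z-scores (`mean_of_z`) is
the default; standardizing the per-author mean logs (`z_of_mean`) is the
alternative — the two differ when authors have different numbers of valid
documents, and the choice is surfaced as a configuration flag rather than
hidden.

`fit_standardized_ols()` fits the association model with the outcome and
all continuous predictors z-scored, categorical controls expanded to
indicator contrasts (first sorted level as reference), QR-based least
squares, and p values from the t distribution with $n - p - 1$ degrees of
freedom. Exactly collinear designs are an error that names the aliased
columns. `fit_ridge()` repeats the fit with an L2 penalty chosen by
10-fold cross-validation over an explicit grid; the solution is the exact
SVD closed form, so a zero penalty reproduces OLS to machine precision —
useful as a multicollinearity robustness check, since volume and the two
speed components are naturally correlated. `decompose_speed_effect()`
fits the volume + speed model and the volume + minimum-required-speed +
circuitousness model side by side, exploiting the exact log-scale
decomposition of speed.

## The synthetic-data module

Nothing in the test suite downloads anything. A `hash_embedding_store()`
maps each word to a deterministic pseudo-random unit vector derived from
the word and a seed; `generate_planted_path()` builds serpentine curves
with controllable spread (`scale`), step size (`step`), and ordering
(`sorted` vs `shuffled` interior) — each curve is rescaled so that the
dim-root volume of its enclosing ellipse is *exactly* proportional to
`scale` (the fold count the step target induces would otherwise couple
shape to scale), which makes `scale` the planted volume by construction
while `step` is honored approximately; and `generate_corpus()` synthesizes
whole corpora over an artificial vocabulary with an author-level outcome
that depends linearly on standardized log volume and log speed plus
Gaussian noise.

The corpus generator drives feature variation with three per-document
knobs: the number of distinct topic words (log-uniform on 40–220), the
width of the sliding topic window words are drawn from (log-uniform on
0.10–0.35 of the topic list; narrow windows make consecutive chunks share
vocabulary, lowering speed while spreading the chunk means), and the
fraction of chunk-sized blocks whose order is shuffled (uniform on 0–1;
shuffling raises speed and circuitousness at exactly fixed content). The
ranges were chosen so that measured log volume and log speed vary as
independently as this document model allows (author-level correlation
about 0.3–0.4): volume and minimum required speed share an intrinsic
driver — both grow with the spread of the chunk cloud — so some
correlation is unavoidable, and the planted-effect recovery tests are run
at a sample size (2000 authors, two 550-word documents each) where the
standard error of a standardized coefficient is about 0.024.

What the generator does *not* emulate: natural-language word frequencies,
syntax, topic structure learned from data, or out-of-vocabulary tokens.
Passing tests therefore demonstrate that the measurement chain is correct
and stable, not that any particular empirical association holds in real
essays.

## Numerical choices and degenerate inputs

* Documents with fewer than 2 points are flagged, not errors; zero-speed
  paths (all points identical) get circuitousness 1 with a degenerate
  flag; a zero minimum with positive speed is an internal error.
* A trailing chunk shorter than half `chunk_size` is merged into the
  preceding chunk (configurable): near-empty chunks have high-variance
  mean embeddings.
* Stopwords are kept by default; tokenization keeps internal apostrophes
  and hyphens and discards other punctuation, and the token regex is
  configurable.
* Consecutive duplicate points are retained — no deduplication rule is
  applied.
* All randomness (heuristic restarts, fold assignment, generators) is
  seeded, never touches the caller's RNG state, and the full configuration
  is serialized into every output file header; identical runs are
  byte-identical.
* Problem sizes used by the shipped checks were chosen to exercise the
  full chain at realistic document scale: oracle comparisons on about a
  hundred instances each, corpus-level checks on 200-document corpora, and
  20 replicates of the 2000-author recovery design.

## Limitations

* The heuristic path solver carries no approximation guarantee; its
  results are bounded between the exact optimum (verified up to 14 points)
  and the observed order by construction.
* The volume normalization is a declared convention; analyses that depend
  on the absolute scale of volume should work on the log scale, where the
  choice only shifts the intercept.
* Chunk embedding is an unweighted mean; frequency weighting or unit
  normalization of word vectors change the geometry and are available as
  options but are not the defaults.
* Embedding quality bounds measurement quality: the package is agnostic
  about where word vectors come from and ships none.
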