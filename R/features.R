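#' Cosine similarity between two vectors
#'
#' Returns `NA` when either vector is an all-zero (out-of-vocabulary) row:
#' a zero vector carries no direction, so treating its similarity as 0 would
#' fabricate information.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`, or `NA`.
#' @export
cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0 || !is.finite(nu) || !is.finite(nv)) return(NA_real_)
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

# full pairwise cosine matrix; zero rows propagate NA
cosine_matrix <- function(V, zero_rows = rowSums(abs(V)) == 0) {
  norms <- sqrt(rowSums(V^2))
  norms[norms == 0] <- NA_real_
  U <- V / norms
  S <- tcrossprod(U)
  S[S > 1] <- 1; S[S < -1] <- -1
  S[zero_rows, ] <- NA_real_
  S[, zero_rows] <- NA_real_
  S
}

#' Consecutive-unit similarity series
#'
#' The cosine similarity between units `i` and `i + k`, ordered along the
#' discourse: the first-order series (`k = 1`, adjacent units, mean =
#' MeanK1) or the second-order series (`k = 2`, one unit in between, mean =
#' MeanK2).
#'
#' @param E A `semcoh_embedding` (or bare numeric matrix).
#' @param k Order: 1 (consecutive) or 2 (one unit in between).
#' @return Numeric vector of length `n - k`, or `NULL` when `n < k + 1`.
#' @export
similarity_series <- function(E, k = 1L) {
  V <- embedding_matrix(E)
  n <- nrow(V)
  stopifnot(k >= 1)
  if (n < k + 1L) return(NULL)
  vapply(seq_len(n - k), function(i) cosine(V[i, ], V[i + k, ]), numeric(1))
}

#' Global mean pairwise similarity
#'
#' Mean cosine over all unordered unit pairs, consecutive or not; invariant
#' under permutation of the units.
#'
#' @param E A `semcoh_embedding` (or bare numeric matrix).
#' @return Mean pairwise cosine, or `NA` when fewer than 2 usable units.
#' @export
global_mean <- function(E) {
  V <- embedding_matrix(E)
  n <- nrow(V)
  if (n < 2L) return(NA_real_)
  S <- cosine_matrix(V)
  mean(S[upper.tri(S)], na.rm = TRUE)
}

embedding_matrix <- function(E) {
  if (inherits(E, "semcoh_embedding")) E$vectors
  else as.matrix(E)
}

#' Distribution descriptors of a similarity series
#'
#' Six statistics of the value distribution, ignoring temporal order:
#' variance (`Var`), maximum (`Peak`), minimum (`Valley`), amplitude
#' (`Amp = Peak - Valley`), skewness (`Skew`) and excess kurtosis
#' (`Kurt`, kurtosis minus 3, so a normal distribution scores 0).
#' Population (biased) moment estimators are used throughout:
#' `Var = m2`, `Skew = m3 / m2^1.5`, `Kurt = m4 / m2^2 - 3` with
#' `mk` the k-th central sample moment. A zero-variance series has
#' undefined standardized moments, so `Skew`/`Kurt` are `NA` there.
#'
#' @param s Numeric series (missing values dropped).
#' @return Named numeric vector `c(Var, Peak, Valley, Amp, Skew, Kurt)`.
#' @export
distribution_descriptors <- function(s) {
  s <- s[is.finite(s)]
  out <- c(Var = NA_real_, Peak = NA_real_, Valley = NA_real_,
           Amp = NA_real_, Skew = NA_real_, Kurt = NA_real_)
  n <- length(s)
  if (n < 1L) return(out)
  out["Peak"] <- max(s); out["Valley"] <- min(s)
  out["Amp"] <- out["Peak"] - out["Valley"]
  if (n < 2L) return(out)
  m <- mean(s); d <- s - m
  m2 <- mean(d^2)
  out["Var"] <- m2
  if (m2 > 0) {
    out["Skew"] <- mean(d^3) / m2^1.5
    out["Kurt"] <- mean(d^4) / m2^2 - 3
  }
  out
}

#' Wave dynamics of a similarity series
#'
#' Treats the similarity series as a signal over narrative time and extracts
#' six dynamical descriptors:
#' \describe{
#'   \item{MCR}{mean-crossing rate: the number of sign changes of
#'     `x_t - mean(x)` between consecutive points, divided by `N - 1`.
#'     A value exactly on the mean is treated as no crossing.}
#'   \item{SSC}{slope-sign-change count: number of interior points where the
#'     slope strictly changes sign, i.e. `(x_t - x_{t-1})(x_{t+1} - x_t) < 0`.}
#'   \item{WL}{waveform length: `sum |x_{t+1} - x_t|`.}
#'   \item{ApEn}{approximate entropy with embedding dimension `m` and
#'     tolerance `r_frac * SD(x)` (population SD); 0 for a constant series.}
#'   \item{ACF}{lag-1 autocorrelation coefficient (standard biased
#'     estimator, as in [stats::acf()]); `NA` for a constant series.}
#'   \item{AcfZcr}{zero-crossing rate of the autocorrelation function over
#'     lags `1..L` with `L = N - 2` (all estimable non-trivial lags): sign
#'     changes between consecutive ACF values divided by `L - 1`.}
#' }
#'
#' @param s Numeric series of length >= 3 (missing values dropped).
#' @param apen_m Approximate-entropy embedding dimension (default 2).
#' @param apen_r Approximate-entropy tolerance as a fraction of the series
#'   SD (default 0.2).
#' @return Named numeric vector `c(MCR, SSC, WL, ApEn, ACF, AcfZcr)`.
#' @export
wave_dynamics <- function(s, apen_m = 2L, apen_r = 0.2) {
  s <- s[is.finite(s)]
  out <- c(MCR = NA_real_, SSC = NA_real_, WL = NA_real_,
           ApEn = NA_real_, ACF = NA_real_, AcfZcr = NA_real_)
  n <- length(s)
  if (n < 2L) return(out)
  d <- diff(s)
  out["WL"] <- sum(abs(d))
  sgn <- sign(s - mean(s))
  out["MCR"] <- sum(sgn[-n] * sgn[-1] < 0) / (n - 1)
  if (n >= 3L) {
    out["SSC"] <- sum(d[-length(d)] * d[-1] < 0)
    out["ApEn"] <- approx_entropy(s, m = apen_m, r = apen_r * sd_pop(s))
    a <- acf_vals(s, lag_max = n - 2L)
    if (length(a) >= 1L && is.finite(a[1])) out["ACF"] <- a[1]
    if (length(a) >= 2L && all(is.finite(a)))
      out["AcfZcr"] <- sum(sign(a[-length(a)]) * sign(a[-1]) < 0) /
        (length(a) - 1)
  }
  out
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# autocorrelation at lags 1..lag_max, standard biased estimator
acf_vals <- function(x, lag_max) {
  n <- length(x)
  lag_max <- min(lag_max, n - 1L)
  if (lag_max < 1L) return(numeric(0))
  d <- x - mean(x)
  denom <- sum(d^2)
  if (denom == 0) return(rep(NA_real_, lag_max))
  vapply(seq_len(lag_max),
         function(k) sum(d[seq_len(n - k)] * d[seq_len(n - k) + k]) / denom,
         numeric(1))
}

# Approximate entropy (regularity statistic), self-matches included:
# ApEn = Phi_m - Phi_{m+1}, Phi_m = mean_i log C_i^m(r).
approx_entropy <- function(x, m = 2L, r) {
  n <- length(x)
  if (n < m + 2L) return(NA_real_)
  if (r == 0 && sd_pop(x) == 0) return(0)
  phi <- function(mm) {
    nv <- n - mm + 1L
    dmax <- matrix(0, nv, nv)
    for (j in seq_len(mm)) {
      xj <- x[seq_len(nv) + j - 1L]
      dmax <- pmax(dmax, abs(outer(xj, xj, "-")))
    }
    mean(log(rowSums(dmax <= r) / nv))
  }
  phi(m) - phi(m + 1L)
}

#' Semantic-graph features
#'
#' Builds an undirected, unweighted graph with units as nodes and an edge
#' between two units whenever their cosine similarity reaches a threshold
#' (no self-loops), then summarizes integration and segregation:
#' \describe{
#'   \item{CC}{mean closeness centrality with Wasserman–Faust component
#'     scaling, so disconnected graphs are handled gracefully; isolated
#'     nodes score 0.}
#'   \item{Cluster}{mean local clustering coefficient; nodes with degree
#'     < 2 (including isolated nodes) score 0.}
#' }
#' The default threshold is the document's own mean pairwise similarity at
#' that level — parameter-free and per-document; a fixed scalar may be
#' supplied instead.
#'
#' @param E A `semcoh_embedding` (or bare numeric matrix).
#' @param threshold `"mean"` (default) or a numeric scalar in `[-1, 1]`.
#' @return Named numeric vector `c(CC, Cluster)`.
#' @export
graph_features <- function(E, threshold = "mean") {
  V <- embedding_matrix(E)
  n <- nrow(V)
  if (n < 2L) return(c(CC = NA_real_, Cluster = NA_real_))
  S <- cosine_matrix(V)
  thr <- if (identical(threshold, "mean")) {
    mean(S[upper.tri(S)], na.rm = TRUE)
  } else as.numeric(threshold)
  A <- (S >= thr)
  A[is.na(A)] <- FALSE
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[!is.finite(cl)] <- 0   # degree-1 nodes
  D <- igraph::distances(g)
  closeness_wf <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(D[i, ]) & seq_len(n) != i)
    ni <- length(reach) + 1L          # component size
    if (ni < 2L) return(0)
    ((ni - 1) / (n - 1)) * ((ni - 1) / sum(D[i, reach]))
  }, numeric(1))
  c(CC = mean(closeness_wf), Cluster = mean(cl))
}

#' Centroid similarity series
#'
#' The similarity of every unit to a topic proxy:
#' the *static* centroid is the mean embedding of all units (the topic of
#' the whole discourse; series length `n`), while the *cumulative* centroid
#' for unit `i` is the mean embedding of all preceding units (topic drift
#' along discourse development; defined from the second unit, length
#' `n - 1`). Centroids are computed on the raw, unnormalized embeddings.
#'
#' @param E A `semcoh_embedding` (or bare numeric matrix).
#' @param mode `"static"` or `"cumulative"`.
#' @return Numeric series, or `NULL` when `n < 2`.
#' @export
centroid_series <- function(E, mode = c("static", "cumulative")) {
  mode <- match.arg(mode)
  V <- embedding_matrix(E)
  n <- nrow(V)
  if (n < 2L) return(NULL)
  if (mode == "static") {
    centroid <- colMeans(V)
    vapply(seq_len(n), function(i) cosine(V[i, ], centroid), numeric(1))
  } else {
    cum <- apply(V, 2L, cumsum)
    vapply(2L:n, function(i) cosine(V[i, ], cum[i - 1L, ] / (i - 1L)),
           numeric(1))
  }
}

#' Word-level perplexity
#'
#' The exponential of the average negative log-likelihood of the token
#' sequence under an autoregressive language model (natural-log convention,
#' so perplexities are base-e).
#'
#' @param lp A log-probability series from [token_logprobs()] (or a bare
#'   numeric vector of natural-log probabilities).
#' @return Perplexity (>= 1 whenever all probabilities are <= 1).
#' @export
word_perplexity <- function(lp) {
  v <- if (inherits(lp, "semcoh_logprobs")) lp$values else as.numeric(lp)
  stopifnot(length(v) >= 1L)
  exp(-mean(v))
}

#' Sentence-level perplexity from next-sentence prediction
#'
#' The exponential of the average negative log-likelihood of the sentence
#' sequence, where each sentence's likelihood is the next-sentence-prediction
#' probability given its predecessor.
#'
#' @param lp A log-probability series from [nsp_probs()] (or a bare numeric
#'   vector of natural-log probabilities).
#' @return Perplexity.
#' @export
nsp_perplexity <- function(lp) {
  v <- if (inherits(lp, "semcoh_logprobs")) lp$values else as.numeric(lp)
  stopifnot(length(v) >= 1L)
  exp(-mean(v))
}
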