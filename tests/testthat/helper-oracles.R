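# Independent brute-force oracles: literal, loop-based re-evaluations of
# every formula, written without reference to the package implementations.

o_cosine <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))

o_mean_k <- function(V, k) {
  vals <- c()
  for (i in seq_len(nrow(V) - k)) vals <- c(vals, o_cosine(V[i, ], V[i + k, ]))
  mean(vals)
}

o_global <- function(V) {
  vals <- c()
  for (i in seq_len(nrow(V) - 1)) for (j in (i + 1):nrow(V))
    vals <- c(vals, o_cosine(V[i, ], V[j, ]))
  mean(vals)
}

o_descriptors <- function(s) {
  n <- length(s); mu <- sum(s) / n
  m2 <- sum((s - mu)^2) / n
  m3 <- sum((s - mu)^3) / n
  m4 <- sum((s - mu)^4) / n
  c(Var = m2, Peak = max(s), Valley = min(s), Amp = max(s) - min(s),
    Skew = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    Kurt = if (m2 > 0) m4 / m2^2 - 3 else NA_real_)
}

o_apen <- function(x, m = 2L, r) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1L
    logC <- numeric(nv)
    for (i in seq_len(nv)) {
      cnt <- 0L
      for (j in seq_len(nv)) {
        d <- max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / nv)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

o_acf_lag <- function(x, k) {
  n <- length(x); mu <- mean(x)
  num <- 0
  for (t in seq_len(n - k)) num <- num + (x[t] - mu) * (x[t + k] - mu)
  num / sum((x - mu)^2)
}

o_dynamics <- function(s, apen_m = 2L, apen_r = 0.2) {
  n <- length(s); mu <- mean(s)
  crossings <- 0L
  for (t in seq_len(n - 1))
    if (sign(s[t] - mu) * sign(s[t + 1] - mu) < 0) crossings <- crossings + 1L
  ssc <- 0L
  for (t in 2:(n - 1))
    if ((s[t] - s[t - 1]) * (s[t + 1] - s[t]) < 0) ssc <- ssc + 1L
  wl <- 0
  for (t in seq_len(n - 1)) wl <- wl + abs(s[t + 1] - s[t])
  sd_p <- sqrt(sum((s - mu)^2) / n)
  a <- sapply(seq_len(n - 2), function(k) o_acf_lag(s, k))
  zc <- 0L
  if (length(a) >= 2)
    for (t in seq_len(length(a) - 1))
      if (sign(a[t]) * sign(a[t + 1]) < 0) zc <- zc + 1L
  c(MCR = crossings / (n - 1), SSC = ssc, WL = wl,
    ApEn = o_apen(s, apen_m, apen_r * sd_p),
    ACF = if (sd_p > 0) a[1] else NA_real_,
    AcfZcr = if (length(a) >= 2) zc / (length(a) - 1) else NA_real_)
}

o_graph <- function(V, thr) {
  n <- nrow(V)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && o_cosine(V[i, ], V[j, ]) >= thr) A[i, j] <- TRUE
  # BFS all-pairs shortest paths
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (src in seq_len(n)) {
    frontier <- src; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- c()
      for (u in frontier) for (v in which(A[u, ]))
        if (!is.finite(D[src, v]) && v != src) { D[src, v] <- d; nxt <- c(nxt, v) }
      frontier <- unique(nxt)
    }
  }
  closeness <- numeric(n)
  for (i in seq_len(n)) {
    reach <- setdiff(which(is.finite(D[i, ])), i)
    ni <- length(reach) + 1
    closeness[i] <- if (ni < 2) 0 else
      ((ni - 1) / (n - 1)) * ((ni - 1) / sum(D[i, reach]))
  }
  clust <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) { clust[i] <- 0; next }
    links <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b]) links <- links + 1
    clust[i] <- 2 * links / (k * (k - 1))
  }
  c(CC = mean(closeness), Cluster = mean(clust))
}

o_centroid <- function(V, mode) {
  n <- nrow(V)
  if (mode == "static") {
    cen <- colSums(V) / n
    sapply(seq_len(n), function(i) o_cosine(V[i, ], cen))
  } else {
    sapply(2:n, function(i) {
      cen <- colSums(V[seq_len(i - 1), , drop = FALSE]) / (i - 1)
      o_cosine(V[i, ], cen)
    })
  }
}

# independent transliteration of the consistency-verdict rule, written as
# explicit case analysis over significance counts
o_verdict <- function(rho, q) {
  if (any(is.na(rho)) || any(is.na(q))) return("Fail")
  n_sig <- sum(q < 0.05)
  n_near <- sum(q < 0.1)
  signs_equal <- function(v) all(v > 0) || all(v < 0)
  if (signs_equal(rho) && n_sig == 3) return("Pass")
  if (signs_equal(rho) && n_sig == 2 && n_near == 3) return("Pass")
  if (n_sig == 2 && signs_equal(rho[q < 0.05])) return("Uncertain")
  "Fail"
}

# fixture probability backends
const_lm <- function(value) function(units) rep(value, length(units))
uniform_lm <- function(vocab) function(units) rep(log(1 / vocab), length(units))
const_nsp <- function(p) function(a, b) p

# fixture POS tagger: tiny lexicon, DET for unknowns
lexicon_tagger <- function(lex) {
  function(words) {
    tags <- lex[tolower(words)]
    tags[is.na(tags)] <- "DET"
    unname(tags)
  }
}
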