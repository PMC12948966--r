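#' Define a vector-embedding backend
#'
#' Backends are injected contracts: any object that can map an ordered list
#' of unit strings to an `n_units x dim` matrix. Real backends (static word
#' vectors, masked-LM token states, sentence encoders) plug in through the
#' same contract the synthetic backend satisfies, so the analysis code never
#' knows which model produced the vectors.
#'
#' Out-of-vocabulary policy is the backend's to choose: subword fallback,
#' zero vector (rows of exact zeros are flagged and treated as missing by all
#' cosine computations), or error. The policy should be recorded in `tag`.
#'
#' @param embed `function(units)` returning a numeric matrix with one row per
#'   unit.
#' @param dim Positive integer, the embedding dimension.
#' @param tag Backend identifier string (model name, OOV policy, layer).
#' @return A `semcoh_backend` object.
#' @export
embedding_backend <- function(embed, dim, tag = "unnamed") {
  stopifnot(is.function(embed), is.numeric(dim), dim >= 1)
  structure(list(embed = embed, dim = as.integer(dim), tag = tag),
            class = "semcoh_backend")
}

#' Embed a unit sequence
#'
#' @param units A [unit_sequence()].
#' @param backend An [embedding_backend()].
#' @return A `semcoh_embedding`: list with `vectors` (n_units x dim matrix),
#'   `level`, `backend_tag`, and `zero_rows` (logical flag per row marking
#'   out-of-vocabulary zero vectors, which downstream cosines treat as
#'   missing rather than fabricating zero similarity).
#' @export
embed_sequence <- function(units, backend) {
  stopifnot(inherits(units, "semcoh_units"), inherits(backend, "semcoh_backend"))
  if (length(units$units) == 0L)
    stop("cannot embed an empty unit sequence", call. = FALSE)
  V <- backend$embed(units$units)
  if (!is.matrix(V) || !is.numeric(V))
    stop("backend '", backend$tag, "' did not return a numeric matrix",
         call. = FALSE)
  if (nrow(V) != length(units$units))
    stop("backend '", backend$tag, "' returned ", nrow(V), " rows for ",
         length(units$units), " units", call. = FALSE)
  if (ncol(V) != backend$dim)
    stop("backend '", backend$tag, "' returned dimension ", ncol(V),
         ", declared ", backend$dim, call. = FALSE)
  embedding_sequence(V, units$level, backend$tag)
}

embedding_sequence <- function(vectors, level, backend_tag = "raw") {
  zero_rows <- rowSums(abs(vectors)) == 0
  structure(list(vectors = vectors, level = level, backend_tag = backend_tag,
                 zero_rows = zero_rows),
            class = "semcoh_embedding")
}

#' @export
print.semcoh_embedding <- function(x, ...) {
  cat(sprintf("<%s embeddings %d x %d [%s]>\n", x$level, nrow(x$vectors),
              ncol(x$vectors), x$backend_tag))
  invisible(x)
}

# -- deterministic hash PRNG ------------------------------------------------
# The synthetic backend must give identical strings identical vectors across
# calls and platforms without touching R's global RNG stream, so it carries
# its own 32-bit generator (FNV-1a string hash -> xorshift32 -> Box-Muller).

fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h - (h > 2147483647) * 4294967296), b)
    h <- h + (h < 0) * 4294967296
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

xorshift32_stream <- function(state, n) {
  # state: unsigned 32-bit value in [1, 2^32-1]; returns n uniforms in (0,1)
  x <- as.integer(state - (state > 2147483647) * 4294967296)
  if (x == 0L) x <- 1L
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- bitwXor(x, bitwShiftL(x, 13L))
    x <- bitwXor(x, bitwShiftR(x, 17L))
    x <- bitwXor(x, bitwShiftL(x, 5L))
    u <- x + (x < 0) * 4294967296
    out[i] <- (u + 0.5) / 4294967296
  }
  out
}

hash_unit_vector <- function(s, dim, seed) {
  state <- bitwXor(
    as.integer(fnv1a32(s) %% 4294967296 - (fnv1a32(s) %% 4294967296 > 2147483647) * 4294967296),
    as.integer((seed * 2654435761) %% 4294967296 -
               ((seed * 2654435761) %% 4294967296 > 2147483647) * 4294967296)
  )
  state <- state + (state < 0) * 4294967296
  n_pairs <- ceiling(dim / 2)
  u <- xorshift32_stream(state, 2L * n_pairs)
  u1 <- u[seq_len(n_pairs) * 2L - 1L]
  u2 <- u[seq_len(n_pairs) * 2L]
  z <- c(sqrt(-2 * log(u1)) * cos(2 * pi * u2),
         sqrt(-2 * log(u1)) * sin(2 * pi * u2))[seq_len(dim)]
  z / sqrt(sum(z^2))
}

#' Deterministic synthetic embedding backend
#'
#' Maps each unit string to a deterministic unit-norm vector derived from a
#' hash of the string and the seed. Identical strings always map to
#' identical vectors; distinct strings behave like independent random unit
#' vectors, whose cosines concentrate around 0 as `dim` grows. R's global
#' random-number stream is not consulted or modified.
#'
#' @param units A [unit_sequence()], or a character vector.
#' @param dim Embedding dimension (>= 2).
#' @param seed Integer seed controlling the hash stream.
#' @return A `semcoh_embedding`.
#' @export
synthetic_embed <- function(units, dim = 64L, seed = 1L) {
  if (inherits(units, "semcoh_units")) {
    level <- units$level
    strings <- units$units
  } else {
    level <- "token"
    strings <- as.character(units)
  }
  stopifnot(dim >= 2)
  if (length(strings) == 0L)
    stop("cannot embed an empty unit sequence", call. = FALSE)
  V <- t(vapply(strings, hash_unit_vector, numeric(dim),
                dim = dim, seed = seed, USE.NAMES = FALSE))
  embedding_sequence(V, level, sprintf("synthetic-hash(dim=%d,seed=%d)", dim, seed))
}

#' Synthetic backend as an [embedding_backend()] contract object
#' @inheritParams synthetic_embed
#' @export
synthetic_backend <- function(dim = 64L, seed = 1L) {
  embedding_backend(
    embed = function(units) synthetic_embed(units, dim = dim, seed = seed)$vectors,
    dim = dim, tag = sprintf("synthetic-hash(dim=%d,seed=%d)", dim, seed)
  )
}

# -- probability series -----------------------------------------------------

logprob_series <- function(values, granularity = c("token", "sentence_pair")) {
  granularity <- match.arg(granularity)
  stopifnot(is.numeric(values), length(values) >= 1L)
  structure(list(values = as.numeric(values), granularity = granularity),
            class = "semcoh_logprobs")
}

#' Score a token sequence with an autoregressive language model
#'
#' @param units A [unit_sequence()] (token level) to score.
#' @param lm Autoregressive-LM contract: `function(units)` returning one
#'   natural-log probability `log p(unit_i | units_<i)` per scored token
#'   under the model's own conditioning (first-token handling is the
#'   backend's, e.g. begin-of-sequence conditioning).
#' @return A log-probability series with `granularity = "token"`.
#' @export
token_logprobs <- function(units, lm) {
  stopifnot(inherits(units, "semcoh_units"), is.function(lm))
  if (length(units$units) == 0L)
    stop("cannot score an empty unit sequence", call. = FALSE)
  lp <- lm(units$units)
  bad <- which(!is.finite(lp))
  if (length(bad))
    stop("non-finite log-probability at position ", bad[1], call. = FALSE)
  if (any(lp > 0))
    stop("log-probability above 0 at position ", which(lp > 0)[1],
         call. = FALSE)
  logprob_series(lp, "token")
}

#' Score sentence adjacency with a next-sentence-prediction head
#'
#' @param sentences A sentence-level [unit_sequence()] with >= 2 sentences.
#' @param nsp Next-sentence contract: `function(a, b)` returning the binary
#'   classifier's probability in `(0, 1]` that sentence `b` follows `a`.
#' @return A log-probability series with `granularity = "sentence_pair"` and
#'   one value per adjacent pair (length `n - 1`).
#' @export
nsp_probs <- function(sentences, nsp) {
  stopifnot(inherits(sentences, "semcoh_units"), is.function(nsp))
  s <- sentences$units
  if (length(s) < 2L)
    stop("next-sentence prediction needs at least 2 sentences", call. = FALSE)
  p <- vapply(seq_len(length(s) - 1L),
              function(i) nsp(s[i], s[i + 1L]), numeric(1))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("next-sentence probability outside (0, 1] at pair ",
         which(!is.finite(p) | p <= 0 | p > 1)[1], call. = FALSE)
  logprob_series(log(p), "sentence_pair")
}
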