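#' Spearman rank correlation with a t-approximation p-value
#'
#' Average-rank tie handling and a two-sided p-value from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom, the convention of standard correlation toolkits.
#' Missing values are removed pairwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum number of complete pairs (default 4).
#' @return List with `rho`, `p` and `n` (complete pairs). `rho` is `NA` when
#'   either variable is constant after pairwise deletion.
#' @export
spearman <- function(x, y, min_n = 4L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini–Hochberg q-values
#'
#' Step-up false-discovery-rate correction. In the cross-language
#' evaluation, the family is the three languages of one feature.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values in the input order.
#' @export
fdr_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Classify cross-language consistency of one feature
#'
#' Verdict rule over the three languages' correlation signs and FDR-corrected
#' q-values, with significance at `q < 0.05` and near-significance at
#' `q < 0.1`:
#' \describe{
#'   \item{Pass}{identical signs in all three languages AND (3 significant,
#'     or 2 significant plus the third near-significant).}
#'   \item{Uncertain}{exactly 2 significant languages, with identical signs
#'     in those two, and not a Pass. The third language's sign is
#'     unconstrained.}
#'   \item{Fail}{anything else, including any missing correlation.}
#' }
#'
#' @param rho Numeric vector of 3 correlation coefficients.
#' @param q Numeric vector of 3 q-values.
#' @return `"Pass"`, `"Uncertain"` or `"Fail"`.
#' @export
classify_consistency <- function(rho, q) {
  stopifnot(length(rho) == 3L, length(q) == 3L)
  if (any(!is.finite(rho)) || any(!is.finite(q))) return("Fail")
  sig <- q < 0.05
  near <- q < 0.1
  same_sign_all <- length(unique(sign(rho))) == 1L && all(sign(rho) != 0)
  if (same_sign_all && (all(sig) || (sum(sig) == 2L && all(near))))
    return("Pass")
  if (sum(sig) == 2L) {
    s <- sign(rho[sig])
    if (s[1] == s[2] && s[1] != 0) return("Uncertain")
  }
  "Fail"
}

#' Evaluate every feature against ratings across three language corpora
#'
#' For each feature: one Spearman correlation with the human coherence
#' rating per corpus (pairwise-complete), one Benjamini–Hochberg family over
#' the three languages' p-values, and one [classify_consistency()] verdict.
#' A feature missing in more than half of any corpus is a `Fail` with reason
#' `"insufficient data"`.
#'
#' @param tables Named list of 3 data frames (names = language tags), each
#'   with the feature columns and a `rating` column.
#' @param features Feature columns to evaluate; defaults to
#'   [battery_names()] intersected with the common columns.
#' @return Data frame with one row per feature: `rho_*`, `p_*`, `q_*` per
#'   language, `verdict`, and `reason`; sorted Pass, Uncertain, Fail and by
#'   maximum absolute correlation within verdict.
#' @export
evaluate_corpora <- function(tables, features = NULL) {
  stopifnot(is.list(tables), length(tables) == 3L)
  langs <- names(tables)
  if (is.null(langs) || any(!nzchar(langs)))
    langs <- names(tables) <- paste0("lang", 1:3)
  common <- Reduce(intersect, lapply(tables, names))
  if (!("rating" %in% common))
    stop("every table needs a `rating` column", call. = FALSE)
  if (is.null(features)) features <- intersect(battery_names(), common)
  if (length(features) == 0L)
    stop("no shared feature columns to evaluate", call. = FALSE)

  res <- lapply(features, function(f) {
    rho <- p <- numeric(3)
    insufficient <- FALSE
    for (i in 1:3) {
      tab <- tables[[i]]
      if (mean(!is.finite(tab[[f]])) > 0.5) insufficient <- TRUE
      st <- spearman(tab[[f]], tab$rating)
      rho[i] <- st$rho; p[i] <- st$p
    }
    q <- fdr_bh(p)
    verdict <- if (insufficient) "Fail" else classify_consistency(rho, q)
    reason <- if (insufficient) "insufficient data" else ""
    stats::setNames(
      data.frame(feature = f, t(rho), t(p), t(q), verdict = verdict,
                 reason = reason, stringsAsFactors = FALSE),
      c("feature", paste0("rho_", langs), paste0("p_", langs),
        paste0("q_", langs), "verdict", "reason"))
  })
  out <- do.call(rbind, res)
  rho_cols <- paste0("rho_", langs)
  max_abs <- apply(abs(as.matrix(out[rho_cols])), 1L, max)
  ord <- order(match(out$verdict, c("Pass", "Uncertain", "Fail")), -max_abs)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
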