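DESC_NAMES <- c("Var", "Peak", "Valley", "Amp", "Skew", "Kurt")
DYN_NAMES  <- c("MCR", "SSC", "WL", "ApEn", "ACF", "AcfZcr")
SERIES_STATS <- c("MeanK1", DESC_NAMES, DYN_NAMES)       # 13 per series
LEVEL_MEASURES <- c("MeanK1", "MeanK2", "Global",
                    DESC_NAMES, DYN_NAMES, "CC", "Cluster",
                    paste0("stat_", SERIES_STATS),
                    paste0("cuml_", SERIES_STATS))       # 43 per level
LEVEL_PREFIX <- c(lexical = "FT", token = "BERT", sentence = "Sent")

#' Names of the full feature battery
#'
#' The battery holds 43 measures per unit level — 3 averaged similarities
#' (MeanK1, MeanK2, Global), 6 distribution descriptors and 6 wave-dynamics
#' measures of the first-order similarity series, 2 semantic-graph measures
#' (CC, Cluster), and 13 measures (mean + descriptors + dynamics) for each
#' of the static and cumulative centroid series — for the lexical (`FT_`),
#' token (`BERT_`) and sentence (`Sent_`) levels, plus the two probability
#' measures `Word_PPL` and `BERT_NSP_PPL`: 43 x 3 + 2 = 131 in total.
#' The level prefixes follow the naming convention of the field (fastText
#' vectors for content words, BERT-family token states, sentence encoders).
#'
#' @return Character vector of the 131 feature names, in canonical order.
#' @export
battery_names <- function() {
  c(as.vector(vapply(LEVEL_PREFIX, function(p)
      paste(p, LEVEL_MEASURES, sep = "_"), character(length(LEVEL_MEASURES)))),
    "Word_PPL", "BERT_NSP_PPL")
}

# the 43 level measures for one embedding sequence (assumed usable)
level_measures <- function(E, graph_threshold, apen_m, apen_r) {
  s1 <- similarity_series(E, 1L)
  s2 <- similarity_series(E, 2L)
  series_stats <- function(s) {
    c(MeanK1 = if (is.null(s)) NA_real_ else mean(s, na.rm = TRUE),
      distribution_descriptors(s),
      wave_dynamics(s, apen_m = apen_m, apen_r = apen_r))
  }
  out <- c(
    MeanK1 = if (is.null(s1)) NA_real_ else mean(s1, na.rm = TRUE),
    MeanK2 = if (is.null(s2)) NA_real_ else mean(s2, na.rm = TRUE),
    Global = global_mean(E),
    distribution_descriptors(s1),
    wave_dynamics(s1, apen_m = apen_m, apen_r = apen_r),
    graph_features(E, threshold = graph_threshold)
  )
  st <- series_stats(centroid_series(E, "static"))
  cu <- series_stats(centroid_series(E, "cumulative"))
  names(st) <- paste0("stat_", SERIES_STATS)
  names(cu) <- paste0("cuml_", SERIES_STATS)
  c(out, st, cu)[LEVEL_MEASURES]
}

#' Extract the full 131-measure feature battery for one document
#'
#' Computes every semantic measure on the supplied embedding sequences and
#' both probability measures on the supplied log-probability series. The
#' result always carries exactly 131 named entries; measures that cannot be
#' computed are `NA`, never silently 0. A level whose unit count fails the
#' minimum-unit rule (fewer than `min_units` units) has all 43 of its
#' measures missing. Degenerate inputs never raise: missingness reasons are
#' recorded in the `"missing_reason"` attribute.
#'
#' @param lexical,token,sentence `semcoh_embedding` objects (or bare
#'   matrices) for the three unit levels; `NULL` when unavailable.
#' @param lp_token Token log-probability series ([token_logprobs()]) for
#'   `Word_PPL`; `NULL` when unavailable.
#' @param lp_nsp Sentence-pair log-probability series ([nsp_probs()]) for
#'   `BERT_NSP_PPL`; `NULL` when unavailable.
#' @param min_units Minimum usable unit count per level (default 4).
#' @param graph_threshold Graph edge threshold: `"mean"` or a scalar.
#' @param apen_m,apen_r Approximate-entropy parameters (embedding dimension
#'   and tolerance fraction of the series SD).
#' @return Named numeric vector of length 131 (class `semcoh_battery`), with
#'   a `"missing_reason"` attribute naming why any entry is `NA`.
#' @export
extract_battery <- function(lexical = NULL, token = NULL, sentence = NULL,
                            lp_token = NULL, lp_nsp = NULL,
                            min_units = 4L, graph_threshold = "mean",
                            apen_m = 2L, apen_r = 0.2) {
  nm <- battery_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  reasons <- character(0)
  embs <- list(lexical = lexical, token = token, sentence = sentence)
  for (lev in names(embs)) {
    prefix <- LEVEL_PREFIX[[lev]]
    keys <- paste(prefix, LEVEL_MEASURES, sep = "_")
    E <- embs[[lev]]
    if (is.null(E)) {
      reasons[keys] <- "level not supplied"
      next
    }
    n <- nrow(embedding_matrix(E))
    if (!check_min_units(n, min_units)) {
      reasons[keys] <- sprintf("only %d units (< %d)", n, min_units)
      next
    }
    out[keys] <- level_measures(E, graph_threshold, apen_m, apen_r)
  }
  if (!is.null(lp_token)) out["Word_PPL"] <- word_perplexity(lp_token)
  else reasons["Word_PPL"] <- "no token log-probabilities"
  if (!is.null(lp_nsp)) out["BERT_NSP_PPL"] <- nsp_perplexity(lp_nsp)
  else reasons["BERT_NSP_PPL"] <- "no next-sentence probabilities"
  still_na <- names(out)[is.na(out) & !(names(out) %in% names(reasons))]
  reasons[still_na] <- "undefined on degenerate series"
  structure(out, missing_reason = reasons, class = "semcoh_battery")
}

#' @export
print.semcoh_battery <- function(x, ...) {
  cat(sprintf("<feature battery: %d measures, %d missing>\n",
              length(x), sum(is.na(x))))
  invisible(x)
}
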