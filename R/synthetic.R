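#' Specification for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic generators, which emulate the
#' statistical structure the analyses assume: unit-embedding sequences with
#' a topic-adherence/persistence random walk on the unit sphere, ordinal
#' ratings produced from latent coherence through thresholds on a noisy
#' latent scale, group-shifted clinical cohorts, token log-probability
#' series with a stated mean negative log-likelihood, and parcel gradient
#' values with stated network means. Latent coherence is operationalized as
#' the topic-adherence weight `topic_weight` — a modeling choice of this
#' package, not an empirical claim.
#'
#' @param seed Integer master seed; all randomness flows from it.
#' @param n_docs Number of documents for corpus generation.
#' @param units_range Integer range (min, max) of units per document.
#' @param dim Embedding dimension (>= 8).
#' @param topic_weight Topic-adherence weight `alpha` in `[0, 1]`: how
#'   strongly every unit is pulled toward the document's topic vector.
#' @param persistence Persistence weight `beta` in `[0, 1]`: how strongly a
#'   unit carries over its predecessor's direction. Requires
#'   `alpha + beta <= 1`.
#' @param noise_sd Total standard deviation of the spherical innovation.
#' @param alpha_range Range over which per-document topic adherence varies
#'   in rated-corpus generation (this variation is the planted coherence
#'   signal).
#' @param rating_cuts Increasing thresholds on the standardized latent
#'   scale producing ratings 1/2/3.
#' @param rating_noise_sd SD of the rating noise on the latent scale.
#' @param mean_nll Mean negative log-likelihood of generated token
#'   log-probability series (expected word perplexity `exp(mean_nll)` as the
#'   spread vanishes).
#' @param nll_sd SD of the token negative log-likelihoods.
#' @param group_sizes Named group sizes for cohort generation (defaults
#'   mirror a typical psychosis-spectrum study: HC 29, CHR 18, FEP 29,
#'   CS 18).
#' @param group_effects Named latent-coherence shifts per group relative to
#'   HC, on the probit latent scale.
#' @param rating_scale Slope mapping latent coherence to the 1–3 rating
#'   scale in cohort generation.
#' @param sample_noise_sd SD of per-sample rating noise in cohort
#'   generation (0 makes the label-generating process exactly the ordered
#'   probit model).
#' @param network_means Named mean principal-gradient value per network.
#' @param network_sd SD of parcel gradient values around their network mean.
#' @param parcels_per_network Parcels per network.
#' @return A `semcoh_genspec` list.
#' @export
generator_spec <- function(seed = 1L,
                           n_docs = 150L,
                           units_range = c(8L, 14L),
                           dim = 32L,
                           topic_weight = 0.4,
                           persistence = 0.3,
                           noise_sd = 0.4,
                           alpha_range = c(0.05, 0.65),
                           rating_cuts = c(-0.5, 0.5),
                           rating_noise_sd = 1.0,
                           mean_nll = log(40),
                           nll_sd = 0.5,
                           group_sizes = c(HC = 29L, CHR = 18L, FEP = 29L, CS = 18L),
                           group_effects = c(HC = 0, CHR = -0.2, FEP = -0.9, CS = -0.5),
                           rating_scale = 0.35,
                           sample_noise_sd = 0.2,
                           network_means = c(VN = -4, SMN = -3.5, DAN = -1,
                                             VAN = 0, LN = 1, FPN = 2, DMN = 4),
                           network_sd = 0.5,
                           parcels_per_network = 20L) {
  stopifnot(dim >= 8, topic_weight >= 0, topic_weight <= 1,
            persistence >= 0, persistence <= 1)
  if (topic_weight + persistence > 1)
    stop("invalid spec: topic_weight + persistence > 1", call. = FALSE)
  if (is.unsorted(rating_cuts, strictly = TRUE))
    stop("invalid spec: rating cut-points must be strictly increasing",
         call. = FALSE)
  stopifnot(mean_nll >= 0, units_range[1] >= 2, units_range[2] >= units_range[1])
  structure(as.list(environment()), class = "semcoh_genspec")
}

rand_unit <- function(dim) {
  v <- stats::rnorm(dim)
  v / sqrt(sum(v^2))
}

#' Generate one synthetic document's embedding sequence
#'
#' Draws a topic vector `t` once, then evolves units on the unit sphere:
#' `u_1` is a random unit vector and
#' `u_i = normalize(alpha * t + beta * u_{i-1} + eps_i)` with spherical
#' Gaussian innovation of total SD `noise_sd`. Larger `alpha` (topic
#' adherence) makes every unit hug the topic — the generator's definition
#' of latent coherence; larger `beta` makes adjacent units similar
#' regardless of topic.
#'
#' @param spec A [generator_spec()].
#' @param n_units Number of units (default drawn from `spec$units_range`).
#' @param alpha,beta Override the spec's topic weight / persistence.
#' @param seed Seed (default `spec$seed`); pass `NA` to use the current RNG
#'   stream (for corpus-level generation under one master seed).
#' @return A `semcoh_embedding` with attributes `latent_coherence`
#'   (= `alpha`) and `topic` (the topic vector).
#' @export
gen_document <- function(spec = generator_spec(), n_units = NULL,
                         alpha = spec$topic_weight, beta = spec$persistence,
                         seed = spec$seed) {
  if (alpha + beta > 1) stop("invalid spec: alpha + beta > 1", call. = FALSE)
  if (!is.na(seed)) set.seed(seed)
  if (is.null(n_units))
    n_units <- sample(spec$units_range[1]:spec$units_range[2], 1L)
  dim <- spec$dim
  topic <- rand_unit(dim)
  per_coord_sd <- spec$noise_sd / sqrt(dim)
  V <- matrix(0, n_units, dim)
  V[1, ] <- rand_unit(dim)
  for (i in seq_len(n_units)[-1]) {
    v <- alpha * topic + beta * V[i - 1L, ] +
      stats::rnorm(dim, sd = per_coord_sd)
    V[i, ] <- v / sqrt(sum(v^2))
  }
  E <- embedding_sequence(V, "token", "synthetic-walk")
  attr(E, "latent_coherence") <- alpha
  attr(E, "topic") <- topic
  E
}

#' Generate a token log-probability series
#'
#' Values are `-(|N(mean_nll, sd)|)`: strictly non-positive natural-log
#' probabilities whose negated mean approaches `mean_nll`, so the expected
#' word perplexity approaches `exp(mean_nll)` as `sd -> 0` (and
#' `exp(mean_nll + sd^2/2)` under the lognormal mean correction for
#' `sd > 0`).
#'
#' @param mean_nll Target mean negative log-likelihood (>= 0).
#' @param sd SD of the negative log-likelihoods.
#' @param n Series length.
#' @param seed Seed; `NA` uses the current RNG stream.
#' @return A token-granularity log-probability series.
#' @export
gen_logprob_series <- function(mean_nll, sd = 0.5, n = 50L, seed = NA) {
  stopifnot(mean_nll >= 0, n >= 1)
  if (!is.na(seed)) set.seed(seed)
  logprob_series(-abs(stats::rnorm(n, mean_nll, sd)), "token")
}

# standardized latent coherence: alpha mapped to mean-0 SD-1 under its
# uniform generating distribution (doc-wise deterministic)
standardize_alpha <- function(alpha, alpha_range) {
  mu <- mean(alpha_range)
  s <- diff(alpha_range) / sqrt(12)
  (alpha - mu) / s
}

#' Generate a rated corpus with a planted coherence effect
#'
#' Per document: topic adherence `alpha` is drawn from `spec$alpha_range`
#' (the latent coherence), embedding sequences are generated at the three
#' unit levels, token log-probabilities and next-sentence probabilities are
#' generated with their means coupled to `alpha` (less coherent documents
#' are less predictable), the 131-measure battery is extracted, and the
#' ordinal rating is produced by adding Gaussian noise to the standardized
#' latent coherence and cutting at `spec$rating_cuts` — an ordered-probit
#' link, matching the downstream model's assumptions. Setting `null = TRUE`
#' holds `alpha` constant so ratings are independent of every feature (a
#' null corpus for error-rate studies).
#'
#' @param spec A [generator_spec()].
#' @param language Language tag stored in the table.
#' @param null Generate a null corpus (no planted effect).
#' @param seed Master seed (default `spec$seed`).
#' @param nll_coupling,nsp_coupling Strength of the predictability coupling
#'   to latent coherence.
#' @return Data frame: `id`, `language`, `rating` (1–3), `latent`, and the
#'   131 feature columns.
#' @export
gen_rated_corpus <- function(spec = generator_spec(), language = "en",
                             null = FALSE, seed = spec$seed,
                             nll_coupling = 1.0, nsp_coupling = 2.0) {
  stopifnot(spec$n_docs >= 1)
  set.seed(seed)
  n <- spec$n_docs
  alpha <- if (null) rep(mean(spec$alpha_range), n)
           else stats::runif(n, spec$alpha_range[1], spec$alpha_range[2])
  mid <- mean(spec$alpha_range)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    beta <- min(spec$persistence, 1 - alpha[i])
    n_sent <- sample(spec$units_range[1]:spec$units_range[2], 1L)
    n_lex <- sample(spec$units_range[1]:spec$units_range[2], 1L)
    n_tok <- 2L * sample(spec$units_range[1]:spec$units_range[2], 1L)
    E_lex <- gen_document(spec, n_lex, alpha[i], beta, seed = NA)
    E_tok <- gen_document(spec, n_tok, alpha[i], beta, seed = NA)
    E_sen <- gen_document(spec, n_sent, alpha[i], beta, seed = NA)
    lp_tok <- gen_logprob_series(
      max(0.05, spec$mean_nll - nll_coupling * (alpha[i] - mid)),
      sd = spec$nll_sd, n = n_tok, seed = NA)
    p_nsp <- stats::plogis(1 + nsp_coupling * (alpha[i] - mid) +
                             stats::rnorm(n_sent - 1L, sd = 0.5))
    lp_nsp <- logprob_series(log(pmin(p_nsp, 1 - 1e-12)), "sentence_pair")
    rows[[i]] <- extract_battery(lexical = E_lex, token = E_tok,
                                 sentence = E_sen, lp_token = lp_tok,
                                 lp_nsp = lp_nsp)
  }
  z <- standardize_alpha(alpha, spec$alpha_range)
  latent_star <- z + stats::rnorm(n, sd = spec$rating_noise_sd)
  rating <- findInterval(latent_star, spec$rating_cuts) + 1L
  feats <- do.call(rbind, lapply(rows, unclass))
  out <- data.frame(id = sprintf("%s_doc%04d", language, seq_len(n)),
                    language = language, rating = rating, latent = alpha,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Generate a synthetic clinical cohort
#'
#' Subjects in four groups with demographic covariates, a latent coherence
#' shifted per group on the probit scale, three per-sample ratings mapped
#' from the latent, symptom scores (PANSS-8 items for FEP/CS, TLI for all
#' groups) generated as monotone transforms of the latent plus noise, and
#' optionally a feature column with per-group slopes (to plant
#' moderation/interaction effects).
#'
#' The label-generating process with `sample_noise_sd = 0` is exactly the
#' ordered probit model the clinical module fits: latent
#' `= shift_group + N(0, 1)`, mean rating `= 2 + rating_scale * latent`,
#' thresholded at 1.8 and 2.2.
#'
#' @param spec A [generator_spec()].
#' @param seed Master seed.
#' @param feature_slopes Optional named per-group slopes of the planted
#'   feature on the latent (e.g. `c(HC = 0, CHR = 0, FEP = 1, CS = 0)`);
#'   when supplied the table gains a `feature` column.
#' @param feature_noise_sd Noise SD of the planted feature.
#' @param symptom_coupling Strength of the (negative) latent-to-symptom
#'   coupling.
#' @return Data frame: `id`, `group` (factor, HC reference), `age`, `sex`,
#'   `education`, `rating_1..3`, `coherence` (ordered factor), `latent`,
#'   PANSS-8 and TLI columns, and optionally `feature`.
#' @export
gen_clinical_cohort <- function(spec = generator_spec(), seed = spec$seed,
                                feature_slopes = NULL,
                                feature_noise_sd = 0.5,
                                symptom_coupling = 1.0) {
  set.seed(seed)
  sizes <- spec$group_sizes
  stopifnot(all(sizes >= 2))
  groups <- factor(rep(names(sizes), sizes), levels = names(sizes))
  n <- length(groups)
  age_med <- c(HC = 22, CHR = 21, FEP = 22, CS = 27)[as.character(groups)]
  age_med[is.na(age_med)] <- 23
  age <- round(pmax(16, age_med + stats::rnorm(n, 0, 3)))
  sex <- stats::rbinom(n, 1L, 0.25)
  education <- stats::rbinom(n, 1L, 0.5)
  latent <- spec$group_effects[as.character(groups)] + stats::rnorm(n)
  ratings <- sapply(1:3, function(s)
    pmin(3, pmax(1, 2 + spec$rating_scale * latent +
                   stats::rnorm(n, sd = spec$sample_noise_sd))))
  coherence <- factor(vapply(seq_len(n), function(i)
    as.character(ordinal_coherence_label(ratings[i, ])), character(1)),
    levels = COHERENCE_LEVELS, ordered = TRUE)
  panss <- sapply(paste0("PANSS8", c("P1", "P2", "P3", "N1", "N4", "N6",
                                     "G5", "G9")), function(item) {
    v <- round(3.5 - symptom_coupling * latent + stats::rnorm(n, sd = 1))
    v <- pmin(7L, pmax(1L, v))
    v[!(groups %in% c("FEP", "CS"))] <- NA_integer_
    v
  })
  tli <- sapply(c("TLIGIOT", "TLIGDIT"), function(item)
    pmin(3, pmax(0, round(0.5 - 0.4 * symptom_coupling * latent +
                            stats::rnorm(n, sd = 0.4), 2))))
  out <- data.frame(id = sprintf("subj%03d", seq_len(n)), group = groups,
                    age = age, sex = sex, education = education,
                    rating_1 = ratings[, 1], rating_2 = ratings[, 2],
                    rating_3 = ratings[, 3], coherence = coherence,
                    latent = latent, stringsAsFactors = FALSE)
  out <- cbind(out, panss, tli)
  if (!is.null(feature_slopes)) {
    slope <- feature_slopes[as.character(groups)]
    slope[is.na(slope)] <- 0
    out$feature <- slope * latent + stats::rnorm(n, sd = feature_noise_sd)
  }
  out
}

#' Generate synthetic parcel gradient values (and optional time series)
#'
#' Per-parcel principal-gradient values drawn `N(mu_network, sd)` around the
#' specified network means; optionally, parcel time series drawn from a
#' block covariance whose blocks follow the network structure (so a
#' diffusion embedding of their FC recovers the block organization).
#'
#' @param spec A [generator_spec()] (supplies network means, SD and parcel
#'   counts).
#' @param seed Master seed.
#' @param timeseries Also generate parcel x time series.
#' @param timepoints Number of timepoints in time-series mode.
#' @param rho_within,rho_between Within-/between-network correlation of the
#'   block covariance.
#' @return List with `values` (per-parcel gradient values), `labels`
#'   (network per parcel), and in time-series mode `ts` (parcels x
#'   timepoints matrix).
#' @export
gen_gradient_data <- function(spec = generator_spec(), seed = spec$seed,
                              timeseries = FALSE, timepoints = 200L,
                              rho_within = 0.5, rho_between = 0.05) {
  set.seed(seed)
  mus <- spec$network_means
  stopifnot(length(mus) >= 2L)
  ppn <- spec$parcels_per_network
  labels <- rep(names(mus), each = ppn)
  values <- stats::rnorm(length(labels), mean = rep(mus, each = ppn),
                         sd = spec$network_sd)
  out <- list(values = values, labels = labels)
  if (timeseries) {
    p <- length(labels)
    C <- matrix(rho_between, p, p)
    for (net in names(mus)) {
      idx <- which(labels == net)
      C[idx, idx] <- rho_within
    }
    diag(C) <- 1
    L <- chol(C)
    # parcels x timepoints, rows correlated per the block structure
    out$ts <- crossprod(L, matrix(stats::rnorm(p * timepoints), p))
  }
  out
}
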