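test_that("generator spec validates its invariants", {
  expect_error(generator_spec(topic_weight = 0.7, persistence = 0.5),
               "topic_weight \\+ persistence")
  expect_error(generator_spec(rating_cuts = c(0.5, -0.5)), "increasing")
  expect_error(gen_document(generator_spec(), alpha = 0.9, beta = 0.9),
               "alpha \\+ beta")
})

test_that("document generation is deterministic and respects the sphere", {
  spec <- generator_spec(seed = 42)
  E1 <- gen_document(spec)
  E2 <- gen_document(spec)
  expect_identical(E1$vectors, E2$vectors)
  expect_equal(unname(sqrt(rowSums(E1$vectors^2))),
               rep(1, nrow(E1$vectors)))
  expect_equal(attr(E1, "latent_coherence"), spec$topic_weight)
})

test_that("topic adherence limits behave as designed", {
  # alpha -> 1, no noise: every unit after the (random) first one collapses
  # onto the topic, so MeanK1 and the static-centroid mean approach 1 as the
  # document grows
  spec <- generator_spec(seed = 1, noise_sd = 1e-8)
  E <- gen_document(spec, n_units = 200, alpha = 0.999, beta = 0.001)
  expect_gt(mean(similarity_series(E, 1)), 0.98)
  expect_gt(mean(centroid_series(E, "static")), 0.98)
  # alpha = beta = 0, high dim: adjacent cosines near 0 on average
  spec0 <- generator_spec(seed = 2, dim = 256, noise_sd = 1)
  m <- replicate(100, {
    E0 <- gen_document(spec0, n_units = 6, alpha = 0, beta = 0, seed = NA)
    mean(similarity_series(E0, 1))
  })
  expect_lt(abs(mean(m)), 0.05)
})

test_that("expected coherence features increase monotonically with topic adherence", {
  spec <- generator_spec(seed = 3, dim = 32)
  alphas <- c(0.05, 0.25, 0.45, 0.65)
  mean_stat <- sapply(alphas, function(a) {
    mean(replicate(40, {
      E <- gen_document(spec, n_units = 10, alpha = a,
                        beta = min(spec$persistence, 1 - a), seed = NA)
      mean(centroid_series(E, "static"))
    }))
  })
  expect_true(all(diff(mean_stat) > 0))
})

test_that("rated corpora carry the planted effect and nulls are null", {
  spec <- generator_spec(seed = 10, n_docs = 120L)
  corp <- gen_rated_corpus(spec, "en")
  expect_equal(nrow(corp), 120L)
  expect_true(all(battery_names() %in% names(corp)))
  expect_true(all(corp$rating %in% 1:3))
  st <- spearman(corp$Sent_stat_MeanK1, corp$rating)
  expect_gt(st$rho, 0.2)
  expect_lt(st$p, 0.01)
  # predictability couplings: higher latent coherence, lower perplexity
  expect_lt(spearman(corp$Word_PPL, corp$rating)$rho, 0)
  # same seed, identical corpus
  corp2 <- gen_rated_corpus(spec, "en")
  expect_identical(corp, corp2)
  # null corpus: latent constant, feature-rating correlation vanishes
  corp0 <- gen_rated_corpus(generator_spec(seed = 11, n_docs = 120L),
                            null = TRUE)
  expect_equal(length(unique(corp0$latent)), 1L)
  expect_gt(spearman(corp0$Sent_stat_MeanK1, corp0$rating)$p, 0.001)
})

test_that("rating generation follows the ordered-probit link", {
  # noise -> 0: rating is a deterministic monotone cut of the latent
  spec <- generator_spec(seed = 12, n_docs = 200L, rating_noise_sd = 1e-9)
  corp <- gen_rated_corpus(spec)
  expect_gt(spearman(corp$latent, corp$rating)$rho, 0.9)
  expect_true(all(diff(tapply(corp$latent, corp$rating, max)) > 0))
})

test_that("clinical cohorts are reproducible with sane group structure", {
  spec <- generator_spec(seed = 9)
  coh <- gen_clinical_cohort(spec)
  expect_equal(as.integer(table(coh$group)[c("HC", "CHR", "FEP", "CS")]),
               c(29L, 18L, 29L, 18L))
  expect_true(all(coh$rating_1 >= 1 & coh$rating_1 <= 3))
  expect_true(is.ordered(coh$coherence))
  # PANSS only on FEP/CS, TLI everywhere
  expect_true(all(is.na(coh$PANSS8P1[coh$group %in% c("HC", "CHR")])))
  expect_true(all(!is.na(coh$PANSS8P1[coh$group %in% c("FEP", "CS")])))
  expect_true(all(is.finite(coh$TLIGIOT)))
  expect_identical(coh, gen_clinical_cohort(spec))
  # planted negative latent-symptom coupling shows in partial Spearman
  sub <- coh[coh$group %in% c("FEP", "CS"), ]
  ps <- partial_spearman(sub$latent, sub$PANSS8P1,
                         sub[, c("age", "sex", "education")])
  expect_lt(ps$r, 0)
})

test_that("log-probability series hit their stated mean negative log-likelihood", {
  lp <- gen_logprob_series(1, sd = 0, n = 20, seed = 1)
  expect_equal(word_perplexity(lp), exp(1))
  expect_equal(word_perplexity(gen_logprob_series(log(4), 0, 10, seed = 2)), 4.0)
  lp3 <- gen_logprob_series(2, sd = 0.5, n = 1e4, seed = 3)
  expect_equal(word_perplexity(lp3), exp(2 + 0.5^2 / 2), tolerance = 0.05 * exp(2.125))
  expect_true(all(lp3$values <= 0))
})

test_that("gradient data reproduce network means and full determinism", {
  spec <- generator_spec(seed = 14)
  gd <- gen_gradient_data(spec)
  for (net in names(spec$network_means)) {
    expect_equal(mean(gd$values[gd$labels == net]),
                 unname(spec$network_means[net]),
                 tolerance = 4 * spec$network_sd /
                   sqrt(spec$parcels_per_network))
  }
  gd2 <- gen_gradient_data(spec)
  expect_identical(gd, gd2)
})
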