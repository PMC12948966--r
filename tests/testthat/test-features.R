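test_that("cosine matches hand values", {
  expect_equal(cosine(c(1, 0), c(1, 0)), 1.0)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine(c(1, 1), c(1, 0)), 1 / sqrt(2), tolerance = 1e-5)
  expect_equal(cosine(c(1, 2), c(3, 4)), cosine(c(3, 4), c(1, 2)))  # symmetry
})

test_that("similarity series and means match hand computation", {
  V <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(similarity_series(V, 1), c(1, 0))
  expect_equal(mean(similarity_series(V, 1)), 0.5)
  expect_equal(similarity_series(V, 2), 0)
  I4 <- matrix(rep(c(1, 0), each = 4), 4, 2)
  expect_equal(similarity_series(I4, 1), rep(1, 3))
  expect_null(similarity_series(V, 3))  # n < k + 1
})

test_that("global mean is the brute-force pair average and permutation-invariant", {
  V <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(global_mean(V), 1 / 3, tolerance = 1e-10)
  set.seed(42)
  W <- matrix(rnorm(8 * 5), 8, 5)
  g <- global_mean(W)
  for (r in 1:5) {
    p <- sample(8)
    expect_equal(global_mean(W[p, ]), g, tolerance = 1e-12)
  }
  expect_true(is.na(global_mean(matrix(1, 1, 3))))
})

test_that("distribution descriptors match population-moment hand values", {
  d <- distribution_descriptors(c(1, 0))
  expect_equal(unname(d[c("Var", "Peak", "Valley", "Amp", "Skew", "Kurt")]),
               c(0.25, 1, 0, 1, 0, -2.0))
  expect_equal(unname(distribution_descriptors(c(0, 0, 1))["Skew"]),
               1 / sqrt(2), tolerance = 1e-5)
  dc <- distribution_descriptors(rep(0.3, 5))
  expect_equal(unname(dc["Var"]), 0)
  expect_equal(unname(dc["Amp"]), 0)
  expect_true(is.na(dc["Skew"]) && is.na(dc["Kurt"]))
})

test_that("wave dynamics match hand-computed formulas", {
  w <- wave_dynamics(c(1, 2, 1, 2))
  expect_equal(unname(w["MCR"]), 1.0)
  expect_equal(unname(w["SSC"]), 2)
  expect_equal(unname(w["WL"]), 3.0)
  expect_equal(unname(w["ACF"]), -0.75)
  w2 <- wave_dynamics(c(1, 3, 2, 4))
  expect_equal(unname(w2["SSC"]), 2)
  expect_equal(unname(w2["WL"]), 5.0)
  wc <- wave_dynamics(rep(2, 6))
  expect_equal(unname(wc["ApEn"]), 0)
  expect_equal(unname(wc["WL"]), 0)
  expect_equal(unname(wc["MCR"]), 0)
  expect_true(is.na(wc["ACF"]))
})

test_that("graph features match hand cases with Wasserman-Faust closeness", {
  idem <- matrix(rep(c(1, 0), each = 3), 3, 2)
  g1 <- graph_features(idem, threshold = 0.5)
  expect_equal(unname(g1["Cluster"]), 1.0)
  expect_equal(unname(g1["CC"]), 1.0)
  orth <- diag(3)
  g2 <- graph_features(orth, threshold = 0.5)
  expect_equal(unname(g2["Cluster"]), 0.0)
  expect_equal(unname(g2["CC"]), 0.0)
  # path A-B-C: B similar to both, A and C orthogonal
  path <- rbind(c(1, 0), c(sqrt(0.5), sqrt(0.5)), c(0, 1))
  g3 <- graph_features(path, threshold = 0.6)
  expect_equal(unname(g3["Cluster"]), 0.0)
  expect_equal(unname(g3["CC"]), 7 / 9, tolerance = 1e-10)
})

test_that("centroid series match running-mean hand computations", {
  V <- rbind(c(1, 0), c(0, 1))
  expect_equal(centroid_series(V, "static"), rep(1 / sqrt(2), 2),
               tolerance = 1e-5)
  W <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(centroid_series(W, "cumulative"), c(1, 0))
  I4 <- matrix(rep(c(1, 0), each = 4), 4, 2)
  expect_equal(centroid_series(I4, "static"), rep(1, 4))
  expect_equal(centroid_series(I4, "cumulative"), rep(1, 3))
  expect_length(centroid_series(W, "static"), 3L)
  expect_length(centroid_series(W, "cumulative"), 2L)
})

test_that("perplexities are exp of mean negative log-likelihood", {
  expect_equal(word_perplexity(rep(-1, 7)), exp(1))
  expect_equal(word_perplexity(log(c(0.5, 0.125))), 4.0)
  expect_equal(word_perplexity(rep(log(1 / 100), 13)), 100.0)
  expect_equal(nsp_perplexity(c(0, 0)), 1.0)
  expect_equal(nsp_perplexity(log(0.25)), 4.0)
  expect_equal(nsp_perplexity(log(c(0.5, 0.125))), 4.0)
})

test_that("battery always carries exactly 131 names with per-level missingness", {
  expect_length(battery_names(), 131L)
  expect_false(anyDuplicated(battery_names()) > 0)
  E <- synthetic_embed(paste0("u", 1:8), dim = 32, seed = 1)
  full <- extract_battery(lexical = E, token = E, sentence = E,
                          lp_token = rep(-1, 10), lp_nsp = log(0.5))
  expect_length(full, 131L)
  expect_equal(sum(is.na(full)), 0L)
  # a 3-unit sentence level is entirely missing, others computed
  E3 <- synthetic_embed(paste0("u", 1:3), dim = 32, seed = 1)
  part <- extract_battery(lexical = E, token = E, sentence = E3,
                          lp_token = rep(-1, 10), lp_nsp = log(0.5))
  sent <- grepl("^Sent_", names(part))
  expect_true(all(is.na(part[sent])))
  expect_false(any(is.na(part[!sent])))
  expect_match(attr(part, "missing_reason")[["Sent_MeanK1"]], "3 units")
  # identical embeddings: MeanK1 = Global = 1, Var = 0
  I5 <- synthetic_embed(rep("same", 5), dim = 16, seed = 2)
  ident <- extract_battery(token = I5)
  expect_equal(unname(ident["BERT_MeanK1"]), 1.0)
  expect_equal(unname(ident["BERT_Global"]), 1.0)
  expect_equal(unname(ident["BERT_Var"]), 0.0)
})

test_that("MeanK1 is order-sensitive while Global is not", {
  spec <- generator_spec(seed = 11, dim = 32)
  changed <- 0L
  for (s in 1:20) {
    E <- gen_document(spec, n_units = 12, alpha = 0.1, beta = 0.8, seed = s)
    V <- E$vectors
    p <- sample(nrow(V))
    m1 <- mean(similarity_series(V, 1))
    m1p <- mean(similarity_series(V[p, ], 1))
    expect_equal(global_mean(V[p, ]), global_mean(V), tolerance = 1e-12)
    if (abs(m1 - m1p) > 1e-8) changed <- changed + 1L
  }
  expect_gte(changed, 18L)  # scrambling almost always changes MeanK1
})

test_that("level features agree with brute-force oracles on random embeddings", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    V <- matrix(rnorm(n * 6), n, 6)
    expect_equal(mean(similarity_series(V, 1)), o_mean_k(V, 1), tolerance = 1e-10)
    expect_equal(mean(similarity_series(V, 2)), o_mean_k(V, 2), tolerance = 1e-10)
    expect_equal(global_mean(V), o_global(V), tolerance = 1e-10)
    thr <- runif(1, -0.2, 0.6)
    expect_equal(graph_features(V, threshold = thr), o_graph(V, thr),
                 tolerance = 1e-10)
    expect_equal(centroid_series(V, "static"), o_centroid(V, "static"),
                 tolerance = 1e-10)
    expect_equal(centroid_series(V, "cumulative"), o_centroid(V, "cumulative"),
                 tolerance = 1e-10)
  }
})
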