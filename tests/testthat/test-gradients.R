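test_that("FC matrix is Fisher-z of Pearson r with clipped diagonal handling", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  set.seed(2)
  base <- rnorm(200)
  ts <- rbind(base, base, rnorm(200))
  fc <- fc_matrix(ts)
  expect_equal(fc, t(fc))
  expect_equal(diag(fc), rep(0, 3), ignore_attr = TRUE)
  expect_equal(fc[1, 2], atanh(1 - 1e-7))   # identical series, clipped
  # constructed pair with known r
  x <- rnorm(5000); y <- 0.5 * x + sqrt(0.75) * rnorm(5000)
  fc2 <- fc_matrix(rbind(x, y))
  expect_equal(fc2[1, 2], atanh(cor(x, y)), tolerance = 1e-10)
  expect_error(fc_matrix(rbind(rep(1, 10), rnorm(10))), "parcel 1")
  # independent noise: off-diagonal z near 0
  set.seed(3)
  fcn <- fc_matrix(matrix(rnorm(20 * 500), 20))
  expect_lt(abs(mean(fcn[upper.tri(fcn)])), 0.02)
})

test_that("group template is the element-wise mean", {
  M <- matrix(rnorm(16), 4)
  expect_equal(group_template(list(M)), M)
  expect_equal(group_template(list(M, -M)), matrix(0, 4, 4))
  A <- matrix(1:16, 4); B <- matrix(0, 4, 4); C <- matrix(2, 4, 4)
  expect_equal(group_template(list(A, B, C)), (A + B + C) / 3)
  expect_error(group_template(list(M, matrix(0, 3, 3))), "mismatch")
})

test_that("diffusion gradients separate blocks and are permutation-equivariant", {
  spec <- generator_spec(seed = 6, network_means = c(A = 0, B = 0),
                         parcels_per_network = 30L)
  gd <- gen_gradient_data(spec, timeseries = TRUE, timepoints = 200,
                          rho_within = 0.6, rho_between = 0.05)
  fc <- fc_matrix(gd$ts)
  gr <- diffusion_gradients(fc, n_components = 3)
  g1 <- gr$gradients[, 1]
  a <- g1[gd$labels == "A"]; b <- g1[gd$labels == "B"]
  expect_true(all(sign(a) == sign(a[1])))
  expect_true(all(sign(b) == -sign(a[1])))
  expect_true(all(diff(abs(gr$lambdas)) <= 1e-12))  # eigenvalue order
  p <- sample(nrow(fc))
  gr2 <- diffusion_gradients(fc[p, p], n_components = 3)
  expect_equal(abs(gr2$gradients), abs(gr$gradients[p, ]), tolerance = 1e-8)
  expect_error(diffusion_gradients(fc, n_components = nrow(fc)), "exceeds")
  ns <- fc; ns[1, 2] <- ns[1, 2] + 1
  expect_error(diffusion_gradients(ns), "symmetric")
})

test_that("Procrustes alignment undoes rotations and sign flips exactly", {
  set.seed(8)
  Tm <- matrix(rnorm(40 * 3), 40)
  expect_equal(procrustes_align(Tm, Tm), Tm, tolerance = 1e-12)
  flipped <- Tm %*% diag(c(-1, 1, -1))
  expect_equal(procrustes_align(flipped, Tm), Tm, tolerance = 1e-10)
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(procrustes_align(Tm %*% qr_, Tm), Tm, tolerance = 1e-10)
  expect_error(procrustes_align(Tm, Tm[, 1:2]), "shape")
})

test_that("dispersion statistics equal hand values and obey invariances", {
  g1 <- c(1, 2, 3, 4, 6)
  labels <- c("A", "A", "A", "B", "B")
  expect_equal(between_network_dispersion(g1, labels, "A", "B"), 3.0)
  expect_equal(between_network_dispersion(rep(2, 4), rep(c("A", "B"), 2),
                                          "A", "B"), 0.0)
  expect_equal(between_network_dispersion(c(5, 9), c("A", "B"), "A", "B"), 4)
  expect_error(between_network_dispersion(g1, labels, "A", "C"), "empty")
  # translation invariance
  expect_equal(between_network_dispersion(g1 + 10, labels, "A", "B"), 3.0)
  expect_equal(within_network_dispersion(c(1, 2, 3)), 2.0)
  expect_equal(within_network_dispersion(rep(0.7, 6)), 0.0)
  expect_equal(within_network_dispersion(c(1, 2, 3) + 5), 2.0)
  expect_equal(within_network_dispersion(3 * c(1, 2, 3)), 9 * 2.0)
  expect_true(is.na(within_network_dispersion(2)))
})

test_that("synthetic network means are recovered by between-network dispersion", {
  spec <- generator_spec(seed = 12, network_means = c(SMN = 2, DMN = 5),
                         network_sd = 0.1, parcels_per_network = 50L)
  gd <- gen_gradient_data(spec)
  d <- between_network_dispersion(gd$values, gd$labels, "SMN", "DMN")
  expect_equal(d, 3.0, tolerance = 0.1)
})

test_that("dispersion-coherence probit finds a planted positive slope", {
  hits <- 0L
  for (s in 1:25) {
    spec <- generator_spec(seed = 400 + s,
                           group_sizes = c(HC = 200L, FEP = 200L),
                           group_effects = c(HC = 0, FEP = -0.6),
                           sample_noise_sd = 0)
    coh <- gen_clinical_cohort(spec, feature_slopes = c(HC = 0.6, FEP = 0.6),
                               feature_noise_sd = 0.5)
    names(coh)[names(coh) == "feature"] <- "dispersion"
    fit <- dispersion_coherence_model(coh, "dispersion")
    zd <- fit$coefficients$z[fit$coefficients$term == "dispersion"]
    if (zd > 1.96) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.8)
  # single-group data: group term dropped with a warning
  spec1 <- generator_spec(seed = 13, group_sizes = c(HC = 120L),
                          group_effects = c(HC = 0))
  coh1 <- gen_clinical_cohort(spec1, feature_slopes = c(HC = 0.8),
                              feature_noise_sd = 0.5)
  names(coh1)[names(coh1) == "feature"] <- "dispersion"
  expect_warning(fit1 <- dispersion_coherence_model(coh1, "dispersion"),
                 "single group")
  expect_false(any(grepl("group", fit1$coefficients$term)))
})
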