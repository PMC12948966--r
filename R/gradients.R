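#' Functional-connectivity matrix from parcel time series
#'
#' Pearson correlation between every pair of parcel time series, Fisher
#' z-transformed (`atanh`) with `r` clipped to `+/-(1 - 1e-7)` first, and
#' the diagonal set to 0.
#'
#' @param ts Numeric matrix, parcels x timepoints (>= 2 timepoints).
#' @return Symmetric parcels x parcels matrix of z-transformed correlations.
#' @export
fc_matrix <- function(ts) {
  ts <- as.matrix(ts)
  stopifnot(ncol(ts) >= 2L)
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant time series at parcel ", which(sds == 0)[1], call. = FALSE)
  r <- stats::cor(t(ts))
  clip <- 1 - 1e-7
  r[r > clip] <- clip; r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Group-template FC matrix
#'
#' Element-wise mean of the individual FC matrices.
#'
#' @param fcs List of FC matrices with identical dimensions.
#' @return The averaged matrix.
#' @export
group_template <- function(fcs) {
  stopifnot(is.list(fcs), length(fcs) >= 1L)
  dims <- vapply(fcs, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("FC matrices have mismatching dimensions", call. = FALSE)
  Reduce(`+`, fcs) / length(fcs)
}

#' Simplified diffusion-map gradient embedding
#'
#' Maps a symmetric FC matrix to a low-dimensional manifold of connectivity
#' gradients: each row is sparsified to its strongest entries, a cosine
#' affinity between the sparsified connectivity profiles is built (as the
#' strictly positive normalized-angle kernel `1 - acos(cos) / pi`, which
#' keeps the diffusion graph connected), the kernel is normalized with the
#' anisotropic
#' diffusion parameter `alpha`, and the leading non-trivial eigenvectors of
#' the resulting diffusion operator — ordered by eigenvalue and scaled by it
#' — form the gradient components. This is a compact reimplementation of
#' the standard diffusion-embedding recipe; it reproduces the qualitative
#' geometry (block separation, principal unimodal-transmodal axis) but makes
#' no claim of numerical parity with any specific published implementation.
#'
#' @param fc Symmetric numeric matrix (z-transformed FC).
#' @param n_components Number of gradients to keep (default 10).
#' @param sparsity Fraction of weakest entries zeroed per row (default 0.9).
#' @param alpha Anisotropic-diffusion normalization exponent (default 0.5).
#' @return A `semcoh_gradients` object: `gradients` (parcels x components,
#'   columns ordered by eigenvalue), `lambdas`, and the parameters used.
#' @export
diffusion_gradients <- function(fc, n_components = 10L, sparsity = 0.9,
                                alpha = 0.5) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  if (!isTRUE(all.equal(fc, t(fc), tolerance = 1e-8)))
    stop("FC matrix must be symmetric", call. = FALSE)
  if (n_components > n - 1L)
    stop("n_components exceeds parcels - 1", call. = FALSE)
  # row-wise sparsification: keep the top (1 - sparsity) fraction per row
  keep <- max(1L, ceiling((1 - sparsity) * n))
  Sp <- t(apply(fc, 1L, function(row) {
    thr <- sort(row, decreasing = TRUE)[keep]
    row[row < thr] <- 0
    row
  }))
  # cosine affinity between sparsified connectivity profiles, mapped to the
  # strictly positive normalized-angle kernel so the diffusion graph stays
  # connected even across unrelated parcel groups
  norms <- sqrt(rowSums(Sp^2))
  norms[norms == 0] <- 1
  A <- tcrossprod(Sp / norms)
  A[A > 1] <- 1; A[A < -1] <- -1
  A <- 1 - acos(A) / pi
  diag(A) <- 1
  # anisotropic normalization then symmetric diffusion operator
  d <- rowSums(A)
  K <- A / outer(d^alpha, d^alpha)
  dk <- rowSums(K)
  M <- K / outer(sqrt(dk), sqrt(dk))
  eig <- eigen(M, symmetric = TRUE)
  # first eigenvector is the trivial stationary direction; drop it
  idx <- seq_len(n_components) + 1L
  phi <- eig$vectors[, idx, drop = FALSE] / sqrt(dk)
  lam <- eig$values[idx]
  G <- sweep(phi, 2L, lam, "*")
  structure(list(gradients = G, lambdas = lam, n_components = n_components,
                 sparsity = sparsity, alpha = alpha),
            class = "semcoh_gradients")
}

#' Orthogonal Procrustes alignment of gradient maps
#'
#' Rotates (and possibly reflects) a subject's gradient map onto a template
#' with the orthogonal transformation minimizing the Frobenius distance; no
#' scaling or translation is applied.
#'
#' @param subject,template Numeric matrices of identical dimensions
#'   (parcels x components), or `semcoh_gradients` objects.
#' @return The aligned subject matrix.
#' @export
procrustes_align <- function(subject, template) {
  S <- if (inherits(subject, "semcoh_gradients")) subject$gradients
       else as.matrix(subject)
  Tm <- if (inherits(template, "semcoh_gradients")) template$gradients
        else as.matrix(template)
  if (!all(dim(S) == dim(Tm)))
    stop("subject and template gradient maps differ in shape", call. = FALSE)
  sv <- svd(crossprod(S, Tm))
  S %*% (sv$u %*% t(sv$v))
}

#' Between-network gradient dispersion
#'
#' Absolute difference in mean principal-gradient value between two
#' functional networks; translation-invariant.
#'
#' @param g1 Per-parcel values of the principal gradient.
#' @param labels Network label per parcel.
#' @param netA,netB Names of the two networks.
#' @return `|mean(g1 in netA) - mean(g1 in netB)|`.
#' @export
between_network_dispersion <- function(g1, labels, netA, netB) {
  stopifnot(length(g1) == length(labels))
  a <- g1[labels == netA]; b <- g1[labels == netB]
  if (length(a) == 0L) stop("network '", netA, "' is empty", call. = FALSE)
  if (length(b) == 0L) stop("network '", netB, "' is empty", call. = FALSE)
  abs(mean(a) - mean(b))
}

#' Within-network gradient dispersion
#'
#' Sum of squared Euclidean distances of every node's first-gradient value
#' to the network centroid (the mean); translation-invariant and quadratic
#' under scaling.
#'
#' @param g Per-parcel first-gradient values of one network.
#' @return `sum((g - mean(g))^2)`, or `NA` with fewer than 2 parcels.
#' @export
within_network_dispersion <- function(g) {
  g <- g[is.finite(g)]
  if (length(g) < 2L) return(NA_real_)
  sum((g - mean(g))^2)
}

#' Ordered probit of coherence on gradient dispersion
#'
#' The linkage model between neural dispersion and linguistic coherence:
#' ordered probit with the dispersion score as a continuous regressor
#' alongside demographics and diagnosis group; optionally with a
#' dispersion-by-group interaction. If the data contain a single group
#' level, the group term is dropped with a warning.
#'
#' @param subjects Data frame with `coherence`, demographics, `group`, and
#'   the dispersion column.
#' @param dispersion_name Name of the dispersion column.
#' @param interaction Add `dispersion x group` terms (default `FALSE`).
#' @param covariates Demographic covariates.
#' @param ref_group Reference group level.
#' @return A `semcoh_probit` fit.
#' @export
dispersion_coherence_model <- function(subjects, dispersion_name,
                                       interaction = FALSE,
                                       covariates = c("age", "sex", "education"),
                                       ref_group = "HC") {
  stopifnot(dispersion_name %in% names(subjects))
  has_group <- "group" %in% names(subjects) &&
    nlevels(droplevels(as.factor(subjects$group))) >= 2L
  if (!has_group && ("group" %in% names(subjects)))
    warning("single group level: dropping group term", call. = FALSE)
  terms <- c(covariates, dispersion_name,
             if (has_group) "group",
             if (interaction && has_group)
               paste0(dispersion_name, ":group"))
  fit_ordered_probit(subjects, terms = terms, ref_group = ref_group)
}
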