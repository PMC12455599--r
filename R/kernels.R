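#' Euclidean pairwise distances between spots
#'
#' @param coords a [spatial_coords()] object or numeric matrix (spots x d).
#' @return A symmetric N x N distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(coords) {
  coords <- unclass(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (nrow(coords) < 2L) stop("need at least two spots")
  as.matrix(stats::dist(coords))
}

new_kernel_matrix <- function(K, family, scale) {
  structure(K, class = c("kernel_matrix", "matrix", "array"),
            spec = list(family = family, scale = scale))
}

#' Gaussian spatial kernel
#'
#' `K_ij = exp(-d_ij^2 / (2 l^2))`; positive semidefinite with unit
#' diagonal for any lengthscale `l > 0`.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param l lengthscale, positive.
#' @return A `kernel_matrix`.
#' @export
gaussian_kernel <- function(D, l) {
  if (!is.numeric(l) || length(l) != 1L || l <= 0) stop("l must be > 0")
  new_kernel_matrix(exp(-unclass(D)^2 / (2 * l^2)), "gaussian", l)
}

#' Cosine spatial kernel
#'
#' `K_ij = cos(2 pi d_ij / phi)`; captures periodic expression patterns.
#' May be indefinite, which the score test's mixture null accommodates.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param phi period, positive.
#' @return A `kernel_matrix`.
#' @export
cosine_kernel <- function(D, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0)
    stop("phi must be > 0")
  new_kernel_matrix(cos(2 * pi * unclass(D) / phi), "cosine", phi)
}

#' Build the bank of spatial kernels
#'
#' Lengthscales / periods are set to quantiles of the nonzero pairwise
#' distance distribution so the bank spans short- to long-range structure;
#' with the defaults this yields 5 Gaussian and 5 Cosine kernels.
#'
#' @param coords a [spatial_coords()] object.
#' @param n_each kernels per family; default 5.
#' @param quantiles distance quantiles used as scales; length `n_each`.
#' @param families kernel families to include.
#' @param max_quantile_n above this many spots the quantiles are estimated
#'   from a deterministic subsample (memory guard).
#' @return A list of `kernel_matrix` objects (length
#'   `n_each * length(families)`).
#' @export
make_kernel_bank <- function(coords, n_each = 5,
                             quantiles = c(0.1, 0.25, 0.5, 0.75, 0.9),
                             families = c("gaussian", "cosine"),
                             max_quantile_n = 5000) {
  coords <- unclass(coords)
  N <- nrow(coords)
  if (N < 3L) stop("need at least three spots for a kernel bank")
  families <- match.arg(families, several.ok = TRUE)
  if (length(quantiles) != n_each)
    quantiles <- seq(min(quantiles), max(quantiles), length.out = n_each)
  if (N > max_quantile_n) {
    idx <- round(seq(1L, N, length.out = max_quantile_n))
    dq <- stats::dist(coords[idx, , drop = FALSE])
  } else {
    dq <- stats::dist(coords)
  }
  dq <- dq[dq > 0]
  if (length(dq) == 0L) stop("all coordinates identical; no distance range")
  scales <- as.numeric(stats::quantile(dq, quantiles))
  D <- pairwise_distances(coords)
  bank <- list()
  for (fam in families) {
    for (s in scales) {
      bank[[length(bank) + 1L]] <-
        if (fam == "gaussian") gaussian_kernel(D, s) else cosine_kernel(D, s)
    }
  }
  names(bank) <- vapply(bank, function(k) {
    sp <- attr(k, "spec"); sprintf("%s_%.4g", sp$family, sp$scale)
  }, character(1))
  bank
}

#' Trimmed eigendecomposition of a kernel bank
#'
#' Smooth spatial kernels are numerically low rank; the score test only
#' needs the eigencomponents whose magnitude is non-negligible. Each kernel
#' is decomposed once and components with `|lambda| < tol * max|lambda|`
#' are dropped (optionally also capped at `max_rank`). Both the test
#' statistic and its null weights are computed from the same trimmed
#' decomposition, so the test stays internally consistent.
#'
#' @param bank list of `kernel_matrix` objects.
#' @param tol relative magnitude threshold for retained eigenvalues.
#' @param max_rank optional hard cap on retained components.
#' @return A list of entries with `values`, `vectors` (N x q), and `spec`.
#' @export
kernel_bank_eigen <- function(bank, tol = 1e-7, max_rank = NULL) {
  lapply(bank, function(K) {
    e <- eigen(unclass(K), symmetric = TRUE)
    keep <- abs(e$values) >= tol * max(abs(e$values))
    if (!is.null(max_rank)) {
      ord <- order(abs(e$values), decreasing = TRUE)
      keep <- keep & seq_along(e$values) %in% ord[seq_len(min(max_rank, length(ord)))]
    }
    list(values = e$values[keep],
         vectors = e$vectors[, keep, drop = FALSE],
         spec = attr(K, "spec"))
  })
}
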