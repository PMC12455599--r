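#' Fit the null (no spatial variance) model for one gene
#'
#' Under the null hypothesis the Gaussian-process model reduces to ordinary
#' least squares of the expression vector on the covariates: residual
#' covariance is `delta * I` only.
#'
#' @param y numeric expression vector (length N).
#' @param X covariate matrix (N x k) including the intercept column; default
#'   intercept only.
#' @return A `null_fit` list with `beta_hat`, `residuals`, `sigma2_hat`
#'   (= r'r / (N - k)), `rank`, `Q` (orthonormal basis of the column space),
#'   and a `degenerate` flag for genes with numerically zero residual
#'   variance.
#' @export
fit_null <- function(y, X = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  if (is.null(X)) X <- matrix(1, N, 1L)
  X <- as.matrix(X)
  if (nrow(X) != N) stop("X rows must match length(y)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank deficient")
  if (N <= ncol(X)) stop("need more spots than covariates")
  beta <- qr.coef(qrX, y)
  r <- qr.resid(qrX, y)
  rss <- sum(r^2)
  sigma2 <- rss / (N - ncol(X))
  degenerate <- rss <= 1e-12 * max(1, sum(y^2))
  structure(list(beta_hat = beta, residuals = r, sigma2_hat = sigma2,
                 rank = qrX$rank, Q = qr.Q(qrX), X = X,
                 degenerate = degenerate),
            class = "null_fit")
}

#' Upper-tail probability of a weighted sum of chi-squares
#'
#' Computes `P(sum_i lambda_i z_i^2 > q)` for iid standard normal `z_i` by
#' numerical inversion of the characteristic function (Imhof's method),
#' which is valid for mixed-sign weights. Falls back to Satterthwaite
#' moment matching if the quadrature fails.
#'
#' @param q observed statistic.
#' @param lambda numeric vector of weights (eigenvalues).
#' @return A list with `p` (clipped to `[0, 1]`) and `method`.
#' @export
chisq_mixture_pvalue <- function(q, lambda) {
  lambda <- lambda[abs(lambda) > 1e-7 * max(abs(lambda), 0)]
  if (length(lambda) == 0L)
    return(list(p = if (q > 0) 0 else 1, method = "degenerate"))
  integrand <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    logrho <- 0.25 * colSums(log1p(lu * lu))
    out <- sin(theta) * exp(-logrho) / u
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  p <- tryCatch({
    v <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                          abs.tol = 1e-12, subdivisions = 1000L,
                          stop.on.error = TRUE)$value
    0.5 + v / pi
  }, error = function(e) NA_real_)
  if (is.na(p) || p < -1e-4 || p > 1 + 1e-4)
    return(list(p = satterthwaite_pvalue(q, lambda), method = "satterthwaite"))
  list(p = min(max(p, 0), 1), method = "imhof")
}

#' Satterthwaite approximation to the chi-square-mixture tail
#'
#' Matches the first two moments with a scaled chi-square; used as a
#' fallback when characteristic-function inversion fails.
#'
#' @inheritParams chisq_mixture_pvalue
#' @return Approximate upper-tail probability.
#' @export
satterthwaite_pvalue <- function(q, lambda) {
  k1 <- sum(lambda)
  k2 <- 2 * sum(lambda^2)
  if (k2 <= 0) return(if (q > 0) 0 else 1)
  if (k1 <= 0) return(1)
  scale <- k2 / (2 * k1)
  df <- 2 * k1^2 / k2
  stats::pchisq(q / scale, df = df, lower.tail = FALSE)
}

# Null weights for the score statistic: eigenvalues of P K P (sigma^2 = 1),
# where P projects off the covariate column space. Uses the trimmed kernel
# decomposition K = U diag(l) U' and the identity that the nonzero
# eigenvalues of P K P equal those of H diag(l) H with H = (I - U'XU-proj)^(1/2),
# a rank-k update, so only a q x q symmetric eigenproblem is solved.
null_weights <- function(keig, Q) {
  U <- keig$vectors
  lam <- keig$values
  q <- length(lam)
  A <- crossprod(U, Q)                       # q x k, Q orthonormal -> G = I
  WW <- crossprod(A)                         # k x k
  ew <- eigen(WW, symmetric = TRUE)
  d <- pmin(pmax(ew$values, 0), 1)
  coef <- ifelse(d > 1e-12, (1 - sqrt(1 - pmin(d, 1))) / d, 0.5)
  S <- ew$vectors %*% (coef * t(ew$vectors))
  WS <- A %*% S                              # q x k
  # H = I - A S A'; C = H diag(lam) H computed via low-rank updates
  LA <- lam * A                              # diag(lam) %*% A
  C <- diag(lam, q) - WS %*% t(LA) - LA %*% t(WS) +
    WS %*% (crossprod(A, LA) %*% t(WS))
  eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
}

#' Variance-component score test against one kernel
#'
#' Tests `H0: sigma_s^2 = 0` in the Gaussian-process model with statistic
#' `T = r' K r` (r the null-model residuals); under the null `T` is a
#' weighted mixture of chi-squares with weights `sigma2_hat` times the
#' eigenvalues of `P K P`.
#'
#' @param fit a [fit_null()] result.
#' @param keig one entry of [kernel_bank_eigen()].
#' @param weights optional precomputed base weights (eigenvalues of `P K P`
#'   at unit variance) to reuse across genes sharing the same covariates.
#' @return A list with `spec`, `statistic`, `p_value`, `method`.
#' @export
score_test <- function(fit, keig, weights = NULL) {
  if (isTRUE(fit$degenerate)) {
    warning("degenerate null fit (zero residual variance); p = 1")
    return(list(spec = keig$spec, statistic = 0, p_value = 1,
                method = "degenerate"))
  }
  if (is.null(weights)) weights <- null_weights(keig, fit$Q)
  ur <- crossprod(keig$vectors, fit$residuals)
  stat <- sum(keig$values * ur^2)
  res <- chisq_mixture_pvalue(stat / fit$sigma2_hat, weights)
  list(spec = keig$spec, statistic = stat, p_value = res$p,
       method = res$method)
}

#' Cauchy combination of p-values
#'
#' Averages Cauchy-transformed p-values; the rule is exact for the minimum
#' tail under arbitrary dependence and returns `p0` when all inputs equal
#' `p0`. Inputs are clipped away from 0 and 1 to keep the tangents finite.
#'
#' @param p numeric vector of p-values.
#' @param clip clipping bound, default `1e-15`.
#' @return Combined p-value in `(0, 1)`.
#' @export
combine_cauchy <- function(p, clip = 1e-15) {
  if (length(p) == 0L) stop("empty p-value list")
  p <- pmin(pmax(p, clip), 1 - clip)
  tstat <- mean(tan((0.5 - p) * pi))
  0.5 - atan(tstat) / pi
}

# Bonferroni-adjusted minimum p, the configurable alternative combiner.
combine_minp <- function(p, clip = 1e-15) {
  if (length(p) == 0L) stop("empty p-value list")
  min(1, length(p) * min(pmax(p, clip)))
}

#' Detect spatially variable genes
#'
#' Step 1 of the framework: per gene, the variance-component score test is
#' run against every kernel in the bank, per-kernel p-values are combined
#' (Cauchy rule by default) and Benjamini-Hochberg controls the FDR across
#' genes.
#'
#' @param expr an [expression_matrix()] (genes x spots, normalized).
#' @param coords a [spatial_coords()] aligned with `expr` columns.
#' @param X optional covariate matrix (N x k); an intercept column is
#'   always included.
#' @param fdr BH false-discovery level for the SVG call; default 0.05.
#' @param combine `"cauchy"` or `"minp"`.
#' @param kernel_eig optional precomputed [kernel_bank_eigen()]; built from
#'   `coords` with defaults when `NULL`.
#' @param ... passed to [make_kernel_bank()].
#' @return An `svg_table` data.frame: `gene_id`, one p-value column per
#'   kernel, `p_combined`, `q_bh`, `is_svg`.
#' @export
detect_svgs <- function(expr, coords, X = NULL, fdr = 0.05,
                        combine = c("cauchy", "minp"),
                        kernel_eig = NULL, ...) {
  combine <- match.arg(combine)
  if (!isTRUE(attr(expr, "normalized")))
    warning("expression matrix is not flagged as normalized")
  al <- align_spots(expr, coords)
  expr <- al$expr; coords <- al$coords
  N <- ncol(expr)
  if (N < 30) warning("fewer than 30 spots; asymptotic p-values unreliable")
  if (is.null(kernel_eig))
    kernel_eig <- kernel_bank_eigen(make_kernel_bank(coords, ...))
  Xfull <- cbind(`(Intercept)` = rep(1, N), X)
  qrX <- qr(Xfull)
  if (qrX$rank < ncol(Xfull)) stop("covariate matrix is rank deficient")
  Q <- qr.Q(qrX)
  k <- ncol(Xfull)
  Y <- unclass(expr)
  R <- Y - (Y %*% Q) %*% t(Q)                 # residual rows per gene
  rss <- rowSums(R^2)
  sigma2 <- rss / (N - k)
  degen <- rss <= 1e-12 * pmax(1, rowSums(Y^2))
  m <- nrow(Y)
  P <- matrix(NA_real_, m, length(kernel_eig))
  for (j in seq_along(kernel_eig)) {
    ke <- kernel_eig[[j]]
    w <- null_weights(ke, Q)
    UR <- R %*% ke$vectors                    # m x q
    stats_j <- drop(UR^2 %*% ke$values)
    for (i in seq_len(m)) {
      P[i, j] <- if (degen[i]) 1 else
        chisq_mixture_pvalue(stats_j[i] / sigma2[i], w)$p
    }
  }
  comb_fun <- if (combine == "cauchy") combine_cauchy else combine_minp
  p_comb <- apply(P, 1L, comb_fun)
  p_comb[degen] <- 1
  q_bh <- stats::p.adjust(p_comb, method = "BH")
  out <- data.frame(gene_id = rownames(Y), P, p_combined = p_comb,
                    q_bh = q_bh, is_svg = q_bh <= fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[1L + seq_along(kernel_eig)] <-
    paste0("p_", names(kernel_eig))
  class(out) <- c("svg_table", "data.frame")
  attr(out, "fdr") <- fdr
  out
}
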