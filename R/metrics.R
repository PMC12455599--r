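#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table under the permutation model. 1 means identical
#' partitions (up to relabeling), values near 0 mean chance agreement.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (anyNA(a) || anyNA(b)) stop("missing labels")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(if (sij == expected) 1 else 0)
  (sij - expected) / (maxi - expected)
}

#' Percentage of abnormal spots
#'
#' For each spot, its `n_neighbors` nearest spots (Euclidean distance, the
#' spot itself excluded, ties broken by ascending spot index) are found; a
#' spot is abnormal when its domain label differs from at least
#' `disagree_min` of them. PAS is the abnormal fraction; low values mean
#' spatially coherent domains.
#'
#' @param labels domain label vector, length N.
#' @param coords [spatial_coords()] or numeric matrix, N rows.
#' @param n_neighbors neighborhood size; default 10.
#' @param disagree_min disagreements needed to call a spot abnormal;
#'   default 6.
#' @return A number in `[0, 1]`.
#' @export
pas <- function(labels, coords, n_neighbors = 10L, disagree_min = 6L) {
  coords <- unclass(coords)
  N <- nrow(coords)
  if (length(labels) != N) stop("labels length must match coordinate rows")
  if (N <= n_neighbors) stop("need more spots than n_neighbors")
  D <- as.matrix(stats::dist(coords))
  abnormal <- logical(N)
  for (i in seq_len(N)) {
    ord <- order(D[i, ], seq_len(N))
    nb <- ord[ord != i][seq_len(n_neighbors)]
    abnormal[i] <- sum(labels[nb] != labels[i]) >= disagree_min
  }
  mean(abnormal)
}
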