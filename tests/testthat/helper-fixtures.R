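# Shared fixture builders; everything is generated in code at test time.

random_coords <- function(n, seed = 1) {
  set.seed(seed)
  spatial_coords(cbind(x = runif(n), y = runif(n)),
                 spot_ids = paste0("s", seq_len(n)))
}

grid_coords <- function(nx = 10, ny = nx) {
  g <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
  spatial_coords(g, spot_ids = paste0("s", seq_len(nrow(g))))
}

random_expr <- function(m, n, seed = 1, spot_ids = paste0("s", seq_len(n))) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(m * n), m, n,
                           dimnames = list(paste0("g", seq_len(m)),
                                           spot_ids)),
                    normalized = TRUE)
}

# 2D rigid motion: rotate by angle and translate
rigid_motion <- function(coords, angle = pi / 6, shift = c(3, -1)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  out <- unclass(coords) %*% R
  out <- sweep(out, 2L, shift, "+")
  spatial_coords(out, spot_ids = rownames(coords))
}

# Brute-force pair-counting adjusted Rand index
ari_bruteforce <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Brute-force PAS: nearest neighbors by distance with index tie-break
pas_bruteforce <- function(labels, coords, k = 10, dmin = 6) {
  cc <- unclass(coords)
  n <- nrow(cc)
  bad <- 0
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((cc - matrix(cc[i, ], n, 2, byrow = TRUE))^2))
    ord <- order(d, seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    if (sum(labels[nb] != labels[i]) >= dmin) bad <- bad + 1
  }
  bad / n
}

# All set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}
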