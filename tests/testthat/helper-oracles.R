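# Small fixture builders and independent oracles shared across test files.

# band matrix from a plain 0/1 matrix; one primer per `per_primer` bands
tiny_bm <- function(values, per_primer = ncol(values), system = "SSR") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("b%03d", seq_len(ncol(values)))
  np <- ceiling(ncol(values) / per_primer)
  primer <- rep(sprintf("P%02d", seq_len(np)), each = per_primer,
                length.out = ncol(values))
  band_matrix(values,
              stats::setNames(primer, colnames(values)),
              stats::setNames(rep_len(system, np), sprintf("P%02d", seq_len(np))))
}

random_bm <- function(n, b, per_primer = 5, prob = 0.5) {
  v <- matrix(rbinom(n * b, 1, prob), n, b)
  # avoid all-zero profiles, which Dice rejects
  v[rowSums(v) == 0, 1] <- 1L
  tiny_bm(v, per_primer)
}

# element-wise Dice oracle: plain double loop over pairs, no linear algebra
dice_matrix_bruteforce <- function(m) {
  X <- m$values
  n <- nrow(X)
  d <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- sum(X[i, ] == 1 & X[j, ] == 1)
    b <- sum(X[i, ] == 1 & X[j, ] == 0)
    cc <- sum(X[i, ] == 0 & X[j, ] == 1)
    d[i, j] <- 1 - 2 * a / (2 * a + b + cc)
  }
  d
}

# ANOVA-identity oracle for one-way AMOVA on Euclidean band data: sums of
# squares computed from raw profiles and group means, never from distances
amova_ss_oracle <- function(m, groups) {
  X <- m$values
  groups <- as.character(groups[rownames(X)])
  gm <- colMeans(X)
  ss_total <- sum(sweep(X, 2, gm)^2)
  ss_within <- sum(vapply(unique(groups), function(g) {
    Xi <- X[groups == g, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }, 0))
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# unrooted topology equality via Robinson-Foulds distance
same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}
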