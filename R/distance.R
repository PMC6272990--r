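#' Dice similarity between two binary band profiles
#'
#' `2a / (2a + b + c)` where `a` counts shared presences and `b`, `c` the
#' presences unique to each profile.  Undefined (error) when both profiles
#' are all-zero — with fully polymorphic dominant panels an all-zero pair
#' signals a corrupt profile, not a biological state.
#'
#' @param x,y equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @export
dice_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  if (2 * a + b + cc == 0)
    stop("Dice coefficient undefined: both profiles are all-zero")
  2 * a / (2 * a + b + cc)
}

#' Pairwise Dice dissimilarity matrix
#'
#' `d = 1 - Dice` for every pair of samples of a band matrix.
#'
#' @param m a [band_matrix()].
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, entries in `[0, 1]`.
#' @export
dissimilarity_matrix <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  X <- m$values
  r <- rowSums(X)
  if (sum(r == 0) >= 2)
    stop("Dice coefficient undefined between all-zero profiles: ",
         paste(rownames(X)[r == 0], collapse = ", "))
  A <- tcrossprod(X)
  S <- 2 * A / outer(r, r, `+`)
  d <- 1 - S
  diag(d) <- 0
  d
}

#' Mean Dice similarity between and within groups
#'
#' Entry (g, h), g != h, is the mean Dice similarity over all cross-group
#' sample pairs; the diagonal holds the mean over within-group pairs (NA for
#' singleton groups, which have no pairs).  This is the conventional way a
#' per-individual fingerprint similarity is summarized into an
#' accession-by-accession or subspecies-by-subspecies similarity table.
#'
#' @param m a [band_matrix()].
#' @param groups group labels, as in [group_diversity()].
#' @return Symmetric numeric matrix over groups.
#' @export
group_mean_similarity <- function(m, groups) {
  groups <- align_groups(m, groups)
  S <- 1 - dissimilarity_matrix(m)
  lev <- unique(unname(groups))
  out <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  for (gi in seq_along(lev)) {
    i <- which(groups == lev[gi])
    for (gj in seq_len(gi)) {
      j <- which(groups == lev[gj])
      if (gi == gj) {
        out[gi, gi] <- if (length(i) > 1) mean(S[i, i][upper.tri(S[i, i])]) else NA_real_
      } else {
        out[gi, gj] <- out[gj, gi] <- mean(S[i, j])
      }
    }
  }
  out
}

#' Squared Euclidean (Hamming) distances between band profiles
#'
#' For 0/1 data the squared Euclidean distance is the number of bands at
#' which two profiles differ.  This is the metric the classical AMOVA
#' formulation operates on for band data.
#'
#' @param m a [band_matrix()].
#' @return Symmetric numeric matrix of nonnegative counts, zero diagonal.
#' @export
squared_euclidean <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  X <- m$values
  r <- rowSums(X)
  d2 <- outer(r, r, `+`) - 2 * tcrossprod(X)
  diag(d2) <- 0
  d2
}
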