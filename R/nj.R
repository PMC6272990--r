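#' Unweighted neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with the standard Q-criterion and
#' the plain-average ("unweighted") distance update
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`.  Deterministic: ties in Q are
#' broken by the lexicographically lowest index pair (i, j), i < j, in the
#' current matrix order.  Negative branch lengths are clamped to zero with
#' the deficit transferred to the sister edge, so each cherry keeps its
#' joint length.
#'
#' @param d symmetric dissimilarity matrix (>= 3 ids, zero diagonal) with
#'   dimnames; a `dist` object is also accepted.
#' @return An unrooted `phylo` tree (ape) with branch lengths; the basal
#'   node is the trifurcation of the final three lineages.
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)   # recovers the split AB | CD with exact branch lengths
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))))
    stop("'d' must be a symmetric square matrix")
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 ids")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  frag <- newick_quote(labs)
  D <- unname(d)

  while (nrow(D) > 3) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], vi, frag[j], vj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    frag <- c(frag[keep], newfrag)
  }
  # closed-form three-point lengths for the final trifurcation
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], v[1], frag[2], v[2], frag[3], v[3])
  ape::read.tree(text = nwk)
}

newick_quote <- function(x) {
  bad <- grepl("[ ()\\[\\]:;,']", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Neighbor-joining tree with band-bootstrap clade support
#'
#' Builds the Dice/NJ tree of a band matrix, then resamples characters with
#' replacement (`unit = "band"` resamples band columns, keeping the total
#' band count; `unit = "primer"` resamples whole primer blocks, keeping the
#' primer count), rebuilds the tree for each replicate, and maps each
#' internal bipartition's replicate frequency (as a percentage) onto the
#' original tree's node labels.
#'
#' @param m a [band_matrix()] with >= 3 samples.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; results are reproducible given it.
#' @param unit resampling unit, `"band"` (default) or `"primer"`.
#' @return The original NJ `phylo` tree with `node.label` set to integer
#'   support percentages in `[0, 100]` (the basal node is left blank) and
#'   attribute `"n_reps"`.
#' @export
bootstrap_support <- function(m, n_reps = 1000, seed = NULL,
                              unit = c("band", "primer")) {
  unit <- match.arg(unit)
  stopifnot(inherits(m, "band_matrix"), n_reps >= 1)
  tree <- nj_tree(dissimilarity_matrix(m))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nb <- ncol(m$values)
  primers <- names(m$primer_system)
  boots <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    cols <- if (unit == "band") {
      sample.int(nb, nb, replace = TRUE)
    } else {
      drawn <- sample(primers, length(primers), replace = TRUE)
      unlist(lapply(drawn, function(p) which(m$band_primer == p)),
             use.names = FALSE)
    }
    vb <- rename_bands(m$values[, cols, drop = FALSE])
    mb <- band_matrix(vb, stats::setNames(unname(m$band_primer)[cols],
                                          colnames(vb)),
                      m$primer_system)
    boots[[k]] <- nj_tree(dissimilarity_matrix(mb))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  pct <- as.integer(round(100 * counts / n_reps))
  lab <- as.character(pct)
  lab[1] <- ""  # basal trifurcation is not a bipartition
  tree$node.label <- lab
  attr(tree, "n_reps") <- n_reps
  tree
}

rename_bands <- function(v) {
  colnames(v) <- sprintf("bs%04d_%s", seq_len(ncol(v)), colnames(v))
  v
}

#' Write a tree to Newick text
#'
#' Standard Newick with branch lengths; bootstrap supports (if present as
#' `node.label`) are written as internal node labels.  The output parses
#' back to an isomorphic tree.
#'
#' @param t a `phylo` tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path) {
  stopifnot(inherits(t, "phylo"))
  ape::write.tree(t, file = path)
  invisible(path)
}
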