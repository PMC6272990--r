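#' One-way distance-based analysis of molecular variance
#'
#' Classical one-way AMOVA on a matrix of squared (Euclidean) distances.
#' With N samples in G groups of sizes n_g:
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
#'       SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij},}
#' `SS_among = SS_total - SS_within`, degrees of freedom `G - 1` and
#' `N - G`, mean squares `MS = SS/df`, variance components
#' `sigma2_within = MS_within` and
#' `sigma2_among = (MS_among - MS_within) / n0` with
#' `n0 = (N - sum(n_g^2)/N) / (G - 1)`.  The Phi statistic is the among
#' share of the total variance.  Significance comes from permuting the
#' sample-to-group assignment: `p = (1 + #{sigma2_among* >= observed}) /
#' (n_perm + 1)`, so p is never exactly 0.
#'
#' A negative among-group component (possible when groups are no more
#' different than random) is reported as-is, with the variance proportions
#' floored at 0 and the result flagged.
#'
#' @param d2 symmetric matrix of squared distances (e.g.
#'   [squared_euclidean()]), samples in dimnames.
#' @param groups group label per sample, as in [group_diversity()]; every
#'   group needs >= 2 members.
#' @param n_perm number of label permutations (>= 0; 0 skips the test).
#' @param seed integer seed for the permutations.
#' @return A list of class `"amova"`: `table` (`data.frame` with rows
#'   Among/Within/Total: df, SS, MS, sigma2, percent), `n0`, `phi`,
#'   `p_value`, `n_perm`, `negative_among` flag.
#' @export
amova_oneway <- function(d2, groups, n_perm = 999, seed = NULL) {
  if (inherits(d2, "dist")) d2 <- as.matrix(d2)
  stopifnot(is.matrix(d2), nrow(d2) == ncol(d2), n_perm >= 0)
  N <- nrow(d2)
  groups <- if (!is.null(rownames(d2)) && !is.null(names(groups)))
    align_groups(list(values = d2), groups) else as.character(groups)
  if (length(groups) != N) stop("'groups' must cover every sample")
  sizes <- table(groups)
  G <- length(sizes)
  if (G < 2) stop("AMOVA needs at least 2 groups")
  if (any(sizes < 2))
    stop("groups with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  idx <- split(seq_len(N), groups)
  comp <- amova_components(d2, idx, N, G, sizes)

  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    hits <- 0L
    for (k in seq_len(n_perm)) {
      perm <- sample.int(N)
      idx_p <- lapply(idx, function(ii) perm[ii])
      comp_p <- amova_components(d2, idx_p, N, G, sizes)
      if (comp_p$sigma_among >= comp$sigma_among - 1e-12) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (n_perm + 1)
  }

  sig <- c(comp$sigma_among, comp$sigma_within)
  prop <- if (sum(pmax(sig, 0)) > 0) pmax(sig, 0) / sum(pmax(sig, 0))
          else c(0, 0)  # degenerate: no variation at all
  tab <- data.frame(
    source = c("Among groups", "Within groups", "Total"),
    df = c(G - 1, N - G, N - 1),
    SS = c(comp$ss_among, comp$ss_within, comp$ss_total),
    MS = c(comp$ss_among / (G - 1), comp$ss_within / (N - G), NA),
    sigma2 = c(sig, sum(sig)),
    percent = c(100 * prop, 100),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n0 = comp$n0,
                 phi = prop[1], p_value = p_value, n_perm = n_perm,
                 negative_among = comp$sigma_among < 0),
            class = "amova")
}

amova_components <- function(d2, idx, N, G, sizes) {
  ss_total <- sum(d2) / (2 * N)                # sum over i<j = sum(d2)/2
  ss_within <- sum(vapply(seq_along(idx), function(g) {
    ii <- idx[[g]]
    sum(d2[ii, ii]) / (2 * length(ii))
  }, 0))
  ss_among <- ss_total - ss_within
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (N - G)
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       n0 = n0, sigma_within = ms_within,
       sigma_among = (ms_among - ms_within) / n0)
}

#' @export
print.amova <- function(x, digits = 4, ...) {
  cat("One-way AMOVA (squared Euclidean distances)\n\n")
  print(x$table, digits = digits, row.names = FALSE)
  cat(sprintf("\nn0 = %.4f  Phi = %.4f", x$n0, x$phi))
  if (!is.na(x$p_value))
    cat(sprintf("  p = %.4g (%d permutations)", x$p_value, x$n_perm))
  if (x$negative_among)
    cat("\nnote: among-group variance component is negative (proportions floored at 0)")
  cat("\n")
  invisible(x)
}

#' AMOVA among countries within one subspecies
#'
#' Restricts the band matrix to the samples of one subspecies, groups them
#' by country of origin and runs [amova_oneway()] on squared Euclidean
#' distances — the by-country decomposition a multi-country subspecies gets
#' in the standard report.
#'
#' @param m a [band_matrix()].
#' @param metadata metadata `data.frame` (see [read_sample_metadata()]).
#' @param subspecies subspecies name to analyse.
#' @param ... passed to [amova_oneway()] (`n_perm`, `seed`).
#' @return An `"amova"` object.
#' @export
amova_by_country <- function(m, metadata, subspecies, ...) {
  md <- metadata[metadata$subspecies == subspecies, , drop = FALSE]
  if (!nrow(md)) stop("no samples for subspecies: ", subspecies)
  countries <- unique(md$country)
  if (length(countries) < 2)
    stop(sprintf("subspecies '%s' spans a single country (%s); a by-country AMOVA needs at least 2",
                 subspecies, paste(countries, collapse = ", ")))
  keep <- intersect(sample_ids(m), md$sample_id)
  sub <- m[keep, ]
  grp <- stats::setNames(md$country[match(keep, md$sample_id)], keep)
  amova_oneway(squared_euclidean(sub), grp, ...)
}
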