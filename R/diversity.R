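#' Dominant-marker allele frequencies under Hardy-Weinberg equilibrium
#'
#' A dominant band cannot distinguish homozygous from heterozygous carriers,
#' so the null-allele frequency q is inferred from the band-absence class.
#' With `method = "sqrt"` (the classical estimator, and the POPGENE dominant
#' model): `q = sqrt(1 - presence_freq)`.  With `method = "lynch_milligan"`,
#' a small-sample bias correction divides the square root by
#' `1 - s / (8x)` where `x = 1 - presence_freq` is the null-phenotype
#' frequency and `s = x(1 - x)/n` its sampling variance; the result is
#' clamped to `[0, 1]`.
#'
#' @param presence_freq band presence proportion(s) in `[0, 1]` (vectorized).
#' @param method `"sqrt"` (default) or `"lynch_milligan"`.
#' @param n sample count behind `presence_freq`; required for
#'   `"lynch_milligan"`.
#' @return A list with numeric vectors `p` (dominant/band allele) and `q`
#'   (null allele), `p + q = 1`.
#' @examples
#' dominant_allele_freq(0.75)   # p = q = 0.5
#' @export
dominant_allele_freq <- function(presence_freq,
                                 method = c("sqrt", "lynch_milligan"),
                                 n = NULL) {
  method <- match.arg(method)
  stopifnot(all(presence_freq >= 0 & presence_freq <= 1))
  x <- 1 - presence_freq
  if (method == "sqrt") {
    q <- sqrt(x)
  } else {
    if (is.null(n) || any(n < 1))
      stop("'lynch_milligan' needs the sample count n")
    s <- x * (1 - x) / n
    q <- ifelse(x == 0, 0, sqrt(x) / (1 - s / (8 * x)))
    q <- pmin(pmax(q, 0), 1)
  }
  list(p = 1 - q, q = q)
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# per-band diversity statistics from allele frequencies and observed states
locus_diversity <- function(p, q, n_states) {
  hom <- p^2 + q^2
  data.frame(Na = n_states,
             Ne = 1 / hom,
             He = 1 - hom,
             I = -(xlogx(p) + xlogx(q)))
}

band_locus_table <- function(m, samples, method, n_override = NULL) {
  pf <- band_frequencies(m, samples)
  n <- if (is.null(n_override)) length(samples) else n_override
  fr <- dominant_allele_freq(pf, method, n = n)
  ld <- locus_diversity(fr$p, fr$q, ifelse(pf > 0 & pf < 1, 2L, 1L))
  cbind(data.frame(band = band_ids(m), presence = unname(pf),
                   p = unname(fr$p), q = unname(fr$q)), ld)
}

#' Grouped dominant-marker diversity report
#'
#' For each group (subspecies, accession, ...) and each band: the presence
#' frequency, the HWE allele frequencies (p, q), the observed allele number
#' Na (2 when both band states occur in the group, else 1), the effective
#' allele number `Ne = 1/(p^2 + q^2)`, Nei's gene diversity
#' `He = 1 - p^2 - q^2` and Shannon's index
#' `I = -(p ln p + q ln q)` (natural log, `0 ln 0 = 0`).  Group rows are
#' locus means over *all* bands of the matrix; the Total row pools all
#' samples.  The diversity partition reports `It` (pooled Shannon index),
#' `Is` (mean within-group index, unweighted across groups by default),
#' `Is/It` and `S' = (It - Is)/It`, so `Is/It + S' = 1`.
#'
#' @param m a [band_matrix()].
#' @param groups group label per sample: either a vector aligned with
#'   `sample_ids(m)` or a named vector/factor indexed by sample id.
#' @param method allele-frequency estimator, see [dominant_allele_freq()].
#' @param weighted if `TRUE`, `Is` (and the Mean row) weight groups by their
#'   sample counts instead of averaging them equally.
#' @return A list of class `"diversity_report"`: `groups` (`data.frame` with
#'   group, n, Na, Ne, He, I, plus Mean and Total rows), `partition` (named
#'   vector It, Is, Is_over_It, S_prime), and `loci` (per-group per-band
#'   tables, for audit).
#' @export
group_diversity <- function(m, groups, method = c("sqrt", "lynch_milligan"),
                            weighted = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(m, "band_matrix"))
  groups <- align_groups(m, groups)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("groups with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  lev <- names(sizes)
  loci <- lapply(lev, function(g)
    band_locus_table(m, sample_ids(m)[groups == g], method))
  names(loci) <- lev
  rows <- do.call(rbind, lapply(lev, function(g) {
    lt <- loci[[g]]
    data.frame(group = g, n = as.integer(sizes[[g]]), Na = mean(lt$Na),
               Ne = mean(lt$Ne), He = mean(lt$He), I = mean(lt$I),
               stringsAsFactors = FALSE)
  }))
  w <- if (weighted) as.numeric(sizes) / sum(sizes) else rep(1 / length(lev), length(lev))
  mean_row <- data.frame(group = "Mean", n = as.integer(sum(sizes)),
                         Na = sum(w * rows$Na), Ne = sum(w * rows$Ne),
                         He = sum(w * rows$He), I = sum(w * rows$I),
                         stringsAsFactors = FALSE)
  total_lt <- band_locus_table(m, sample_ids(m), method)
  total_row <- data.frame(group = "Total", n = nrow(m$values),
                          Na = mean(total_lt$Na), Ne = mean(total_lt$Ne),
                          He = mean(total_lt$He), I = mean(total_lt$I),
                          stringsAsFactors = FALSE)
  It <- total_row$I
  Is <- mean_row$I
  partition <- c(It = It, Is = Is,
                 Is_over_It = if (It > 0) Is / It else NA_real_,
                 S_prime = if (It > 0) (It - Is) / It else NA_real_)
  structure(list(groups = rbind(rows, mean_row, total_row),
                 partition = partition,
                 loci = c(loci, list(Total = total_lt))),
            method = method, weighted = weighted,
            class = "diversity_report")
}

align_groups <- function(m, groups) {
  ids <- sample_ids(m)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (!is.null(names(groups))) {
    miss <- setdiff(ids, names(groups))
    if (length(miss)) stop("samples without a group: ",
                           paste(miss, collapse = ", "))
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("'groups' must be named by sample id or aligned with the samples")
  }
  stats::setNames(groups, ids)
}

#' @export
print.diversity_report <- function(x, digits = 3, ...) {
  cat("Dominant-marker diversity (allele-frequency method:",
      attr(x, "method"), ")\n\n")
  print(x$groups, digits = digits, row.names = FALSE)
  p <- x$partition
  cat(sprintf("\nIt = %.3f  Is = %.3f  Is/It = %.3f  S' = %.3f\n",
              p["It"], p["Is"], p["Is_over_It"], p["S_prime"]))
  invisible(x)
}
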