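#' Polymorphic information content of one locus
#'
#' `PIC = 1 - sum(freqs^2)` over the allele (or fingerprint-pattern)
#' frequency spectrum of a locus.
#'
#' @param freqs nonnegative frequencies summing to 1 (tolerance 1e-9).
#' @return Value in `[0, 1)`.
#' @examples
#' pic_locus(c(0.5, 0.5))      # 0.5
#' pic_locus(rep(1 / 9, 9))    # 0.888...
#' @export
pic_locus <- function(freqs) {
  if (any(freqs < 0)) stop("allele frequencies must be nonnegative")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop(sprintf("allele frequencies sum to %.12g, not 1", sum(freqs)))
  1 - sum(freqs^2)
}

#' Average polymorphic information content of a primer
#'
#' Two readings of "PIC of a multiband primer" are supported.
#' `mode = "pattern"` (default) treats every distinct multiband fingerprint
#' of the primer across samples as one allele of a single multiallelic locus;
#' its frequency spectrum is the pattern counts over the sample count, and
#' the primer's PIC is [pic_locus()] of that spectrum.  `mode = "band"`
#' treats each band as a biallelic dominant locus with phenotype spectrum
#' `{p, 1 - p}` (p = presence frequency), and averages the per-band PIC over
#' the primer's polymorphic bands.
#'
#' The pattern reading is the package default because it is the only one
#' that can exceed the `1 - 1/k` ceiling of a k-band locus and so reach the
#' high per-primer values (> 0.9) typical of multiband SSR fingerprints.
#'
#' @param m a [band_matrix()] with >= 2 samples.
#' @param primer primer name present in `m`.
#' @param mode `"pattern"` or `"band"`.
#' @return PIC value in `[0, 1)`.
#' @export
pic_primer <- function(m, primer, mode = c("pattern", "band")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "band_matrix"))
  if (!primer %in% names(m$primer_system))
    stop("unknown primer: ", primer)
  if (nrow(m$values) < 2) stop("PIC needs at least 2 samples")
  v <- m$values[, m$band_primer == primer, drop = FALSE]
  if (mode == "pattern") {
    patt <- apply(v, 1, paste, collapse = "")
    pic_locus(as.vector(table(patt)) / length(patt))
  } else {
    pf <- colMeans(v)
    poly <- pf > 0 & pf < 1
    if (!any(poly)) return(0)
    mean(vapply(pf[poly], function(p) pic_locus(c(p, 1 - p)), 0))
  }
}

system_bands <- function(m, system) {
  if (is.null(system)) return(band_ids(m))
  primers <- names(m$primer_system)[m$primer_system == system]
  if (!length(primers)) stop("no primers in marker system: ", system)
  band_ids(m)[m$band_primer %in% primers]
}

#' Average band informativeness (Ibav)
#'
#' `Ibav = mean(1 - 2 * |0.5 - p_i|)` over the bands of a marker system,
#' where `p_i` is band i's presence proportion pooled over all samples.
#' Maximal (1) when every band is present in exactly half the samples; 0
#' when every band is monomorphic.
#'
#' @param m a [band_matrix()].
#' @param system marker-system label, or `NULL` for all bands.
#' @return Value in `[0, 1]`.
#' @export
ibav <- function(m, system = NULL) {
  pf <- colMeans(m$values[, system_bands(m, system), drop = FALSE])
  mean(1 - 2 * abs(0.5 - pf))
}

#' Effective multiplex ratio (EMR)
#'
#' Mean number of polymorphic bands per primer of a marker system.
#'
#' @inheritParams ibav
#' @return Nonnegative value.
#' @export
emr <- function(m, system = NULL) {
  ps <- polymorphism_summary(m)
  if (!is.null(system)) {
    ps <- ps[ps$system == system, , drop = FALSE]
    if (!nrow(ps)) stop("no primers in marker system: ", system)
  }
  mean(ps$NPB)
}

#' Marker index
#'
#' `MI = Ibav * EMR`, the standard single-number efficiency score of a
#' marker system.
#'
#' @param ibav average band informativeness.
#' @param emr effective multiplex ratio.
#' @return Their product.
#' @export
marker_index <- function(ibav, emr) ibav * emr

#' Marker-efficiency report
#'
#' Per-primer band counts and PIC, plus per-system summary statistics
#' (primer count, locus totals, PPB, Ibav, EMR, MI) in the layout of the
#' standard marker-comparison tables of dominant-marker studies.
#'
#' @param m a [band_matrix()] with >= 2 samples.
#' @param pic_mode passed to [pic_primer()].
#' @return A list of class `"efficiency_report"` with elements `per_primer`
#'   (`data.frame`: primer, system, TNB, NPB, PPB, PIC) and `per_system`
#'   (`data.frame`: system, n_primers, total_loci, mean_loci_per_primer,
#'   PPB, Ibav, EMR, MI), and attribute `pic_mode`.
#' @export
efficiency_report <- function(m, pic_mode = c("pattern", "band")) {
  pic_mode <- match.arg(pic_mode)
  per_primer <- polymorphism_summary(m)
  per_primer$PIC <- vapply(per_primer$primer, pic_primer, 0, m = m,
                           mode = pic_mode)
  systems <- unique(per_primer$system)
  per_system <- do.call(rbind, lapply(systems, function(s) {
    sub <- per_primer[per_primer$system == s, ]
    ib <- ibav(m, s)
    em <- emr(m, s)
    data.frame(system = s,
               n_primers = nrow(sub),
               total_loci = sum(sub$TNB),
               mean_loci_per_primer = mean(sub$TNB),
               PPB = 100 * sum(sub$NPB) / sum(sub$TNB),
               Ibav = ib, EMR = em, MI = marker_index(ib, em),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_primer = per_primer, per_system = per_system),
            pic_mode = pic_mode, class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, digits = 3, ...) {
  cat("Marker efficiency report (PIC mode:", attr(x, "pic_mode"), ")\n\n")
  print(x$per_system, digits = digits, row.names = FALSE)
  cat(sprintf("\n%d primers; per-primer table in $per_primer\n",
              nrow(x$per_primer)))
  invisible(x)
}
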