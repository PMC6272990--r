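#' Construct a band matrix
#'
#' A band matrix is the central data structure of the package: a samples x
#' bands 0/1 scoring of dominant-marker gels ("1" = band present, "0" =
#' absent), together with a map from each band to the primer (pair) that
#' amplified it and from each primer to a marker system (e.g. `"SSR"`,
#' `"IT-ISJ"`).
#'
#' @param values integer (or logical) matrix, samples in rows and bands in
#'   columns, with unique non-empty row and column names.  Every cell must be
#'   exactly 0 or 1; missing values are rejected.
#' @param band_primer named character vector mapping each band id (names) to
#'   its primer.  Must cover every column of `values`.
#' @param primer_system named character vector mapping each primer (names) to
#'   a marker-system label.  Must cover every primer in `band_primer`.
#'
#' @return An object of class `"band_matrix"`: a list with elements `values`,
#'   `band_primer`, `primer_system`.
#' @examples
#' v <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("b1", "b2", "b3")))
#' bm <- band_matrix(v, c(b1 = "P1", b2 = "P1", b3 = "P2"),
#'                   c(P1 = "SSR", P2 = "IT-ISJ"))
#' @export
band_matrix <- function(values, band_primer, primer_system) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (is.logical(values)) values[] <- as.integer(values)
  storage.mode(values) <- "integer"
  sn <- rownames(values)
  bn <- colnames(values)
  if (is.null(sn) || is.null(bn) || any(!nzchar(sn)) || any(!nzchar(bn)))
    stop("band matrix needs non-empty sample (row) and band (column) names")
  if (anyDuplicated(sn)) stop("duplicate sample ids: ",
                              paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (anyDuplicated(bn)) stop("duplicate band ids: ",
                              paste(unique(bn[duplicated(bn)]), collapse = ", "))
  bad <- which(is.na(values) | !(values %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-binary or missing cell at sample '%s', band '%s'",
                 sn[bad[1, 1]], bn[bad[1, 2]]))
  }
  band_primer <- vapply(band_primer, as.character, "")
  if (!all(bn %in% names(band_primer)))
    stop("bands without a primer assignment: ",
         paste(setdiff(bn, names(band_primer)), collapse = ", "))
  band_primer <- band_primer[bn]
  primer_system <- vapply(primer_system, as.character, "")
  missing_primer <- setdiff(unique(band_primer), names(primer_system))
  if (length(missing_primer))
    stop("primers without a marker-system assignment: ",
         paste(missing_primer, collapse = ", "))
  primer_system <- primer_system[unique(band_primer)]
  structure(list(values = values, band_primer = band_primer,
                 primer_system = primer_system),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d samples x %d bands, %d primers (%s)\n",
              nrow(x$values), ncol(x$values), length(x$primer_system),
              paste(sprintf("%s: %d", names(table(x$primer_system)),
                            table(x$primer_system)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$values)

#' Sample and band identifiers of a band matrix
#' @param m a [band_matrix()] object.
#' @return Character vector of ids, in matrix order.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname sample_ids
#' @export
band_ids <- function(m) colnames(m$values)

#' Subset a band matrix by samples and/or bands
#' @param x a [band_matrix()].
#' @param i,j sample / band indices (any form `[` accepts).
#' @param ... unused.
#' @export
`[.band_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  band_matrix(v, x$band_primer[colnames(v)], x$primer_system)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a band matrix from delimited text
#'
#' The file has two header rows: the first gives the band ids, the second the
#' primer of each band; subsequent rows are one sample each (sample id in the
#' first column).  The delimiter is sniffed from the extension (`.csv` =
#' comma, anything else = tab).  The primer-to-system map comes from a
#' two-column (primer, system) file, or an equivalent named character vector;
#' with `system = NULL` every primer is tagged `"unknown"`.
#'
#' @param path path to the band-matrix file.
#' @param system path to a primer-system table (columns `primer`, `system`),
#'   or a named character vector, or `NULL`.
#' @return A validated [band_matrix()]; band order is preserved as read.
#' @export
read_band_matrix <- function(path, system = NULL) {
  sep <- delim_for(path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3)
    stop("band matrix file needs two header rows and at least one sample row")
  split1 <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  split2 <- strsplit(lines[2], sep, fixed = TRUE)[[1]]
  bands <- split1[-1]
  primers <- split2[-1]
  if (length(primers) != length(bands))
    stop("primer header row does not match the band header row in length")
  body <- strsplit(lines[-(1:2)], sep, fixed = TRUE)
  samples <- vapply(body, `[`, "", 1)
  cells <- lapply(body, function(r) {
    if (length(r) != length(bands) + 1)
      stop(sprintf("sample row '%s' has %d fields, expected %d",
                   r[1], length(r), length(bands) + 1))
    r[-1]
  })
  raw <- do.call(rbind, cells)
  num <- suppressWarnings(matrix(as.integer(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) | !(num %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-binary cell '%s' at sample '%s', band '%s'",
                 raw[bad[1, 1], bad[1, 2]], samples[bad[1, 1]],
                 bands[bad[1, 2]]))
  dimnames(num) <- list(samples, bands)
  if (is.null(system)) {
    ps <- stats::setNames(rep("unknown", length(unique(primers))),
                          unique(primers))
  } else if (is.character(system) && length(system) == 1 && is.null(names(system))) {
    tab <- utils::read.table(system, header = TRUE, sep = delim_for(system),
                             stringsAsFactors = FALSE)
    ps <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  } else {
    ps <- system
  }
  band_matrix(num, stats::setNames(primers, bands), ps)
}

#' Write a band matrix (and optional primer-system table) to delimited text
#'
#' Inverse of [read_band_matrix()]: `write_band_matrix(m, p); read_band_matrix(p)`
#' round-trips bit-identically.
#'
#' @param m a [band_matrix()].
#' @param path output path for the matrix (`.csv` = comma, else tab).
#' @param system_path optional output path for the (primer, system) table.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(m, path, system_path = NULL) {
  sep <- delim_for(path)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample", band_ids(m)), collapse = sep), con)
  writeLines(paste(c("primer", unname(m$band_primer)), collapse = sep), con)
  apply_rows <- cbind(sample_ids(m), m$values)
  writeLines(apply(apply_rows, 1, paste, collapse = sep), con)
  if (!is.null(system_path)) {
    utils::write.table(
      data.frame(primer = names(m$primer_system),
                 system = unname(m$primer_system)),
      system_path, sep = delim_for(system_path), quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab- or comma-delimited table with columns `sample_id`, `accession`,
#' `subspecies`, `country`, `range`, `climate` (extra columns are kept).
#' Optionally checked against a band matrix: every sample of the matrix must
#' resolve to exactly one accession, and accession to subspecies must be a
#' function.
#'
#' @param path path to the metadata file.
#' @param m optional [band_matrix()] to validate against.
#' @return A `data.frame` of metadata.
#' @export
read_sample_metadata <- function(path, m = NULL) {
  md <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, quote = "")
  needed <- c("sample_id", "accession", "subspecies", "country", "range",
              "climate")
  miss <- setdiff(needed, names(md))
  if (length(miss)) stop("metadata misses columns: ", paste(miss, collapse = ", "))
  validate_metadata(md, m)
  md
}

validate_metadata <- function(md, m = NULL) {
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  if (!is.null(m)) {
    unresolved <- setdiff(sample_ids(m), md$sample_id)
    if (length(unresolved))
      stop("samples without metadata: ", paste(unresolved, collapse = ", "))
  }
  acc2ssp <- unique(md[c("accession", "subspecies")])
  if (anyDuplicated(acc2ssp$accession))
    stop("accession maps to more than one subspecies")
  invisible(md)
}

#' Per-primer polymorphism summary
#'
#' For each primer: the total number of bands it amplified (TNB), the number
#' of polymorphic bands (NPB; a band is polymorphic when both presence and
#' absence are observed, i.e. its presence frequency lies strictly between 0
#' and 1), and the percentage of polymorphic bands PPB = 100 * NPB / TNB.
#'
#' @param m a [band_matrix()] with at least two samples.
#' @return A `data.frame` with columns `primer`, `system`, `TNB`, `NPB`,
#'   `PPB`, one row per primer in first-appearance order.
#' @export
polymorphism_summary <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  if (nrow(m$values) < 2)
    stop("polymorphism needs at least 2 samples")
  pf <- colMeans(m$values)
  poly <- pf > 0 & pf < 1
  primers <- names(m$primer_system)
  tnb <- vapply(primers, function(p) sum(m$band_primer == p), 0L)
  npb <- vapply(primers, function(p) sum(poly[m$band_primer == p]), 0L)
  data.frame(primer = primers,
             system = unname(m$primer_system),
             TNB = unname(tnb), NPB = unname(npb),
             PPB = 100 * unname(npb) / unname(tnb),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Presence frequency of every band
#' @param m a [band_matrix()].
#' @param samples optional subset of sample ids.
#' @return Named numeric vector, one presence proportion per band.
#' @export
band_frequencies <- function(m, samples = NULL) {
  v <- if (is.null(samples)) m$values else m$values[samples, , drop = FALSE]
  colMeans(v)
}
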