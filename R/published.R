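#' Published summary tables of the Dactylis SSR / IT-ISJ marker panel
#'
#' Summary statistics, as published, for a dominant-marker diversity study
#' of 196 *Dactylis glomerata* individuals (20 accessions, 9 subspecies)
#' genotyped with 21 SSR and 15 IT-ISJ primer pairs.  The raw band scores
#' were never deposited, so these per-primer and per-group summaries are the
#' finest-grained published record; the package uses them for
#' arithmetic-consistency checks of its own statistics.
#'
#' @param which one of
#'   \describe{
#'     \item{`"primers"`}{per-primer TNB, NPB, PPB and PIC;}
#'     \item{`"systems"`}{per-system efficiency parameters (Ibav, EMR, MI);}
#'     \item{`"diversity"`}{per-subspecies Na, Ne, He, Shannon I (with Mean
#'       and Total rows);}
#'     \item{`"partition"`}{the It / Is / Is-over-It / S' diversity partition;}
#'     \item{`"amova"`}{AMOVA tables (overall and per-subspecies by country);}
#'     \item{`"accessions"`}{the accession panel (code, subspecies, country,
#'       distribution range, climate).}
#'   }
#' @return A `data.frame`.
#' @export
published_summary <- function(which = c("primers", "systems", "diversity",
                                        "partition", "amova", "accessions")) {
  which <- match.arg(which)
  fn <- c(primers = "dactylis_primer_summary.tsv",
          systems = "dactylis_system_efficiency.tsv",
          diversity = "dactylis_subspecies_diversity.tsv",
          partition = "dactylis_diversity_partition.tsv",
          amova = "dactylis_amova.tsv",
          accessions = "dactylis_accessions.tsv")[[which]]
  path <- system.file("extdata", fn, package = "bandpop", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
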