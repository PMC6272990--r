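#' Simulation settings for synthetic band matrices
#'
#' The defaults emulate the design of a dominant-marker diversity study on
#' *Dactylis glomerata*: 20 accessions (populations) of 6-10 diploid plants
#' each (196 in total), genotyped with 21 SSR and 15 IT-ISJ primer pairs,
#' each primer amplifying 3-13 scored bands.  Divergence among populations
#' follows the Balding-Nichols model with a single parameter `divergence`
#' (an Fst analogue, default 0.2).
#'
#' @param n_pops number of populations (accessions).
#' @param samples_per_pop integer vector of per-population sample counts
#'   (recycled to `n_pops`).  The default gives 16 populations of 10 and 4 of
#'   9 diploids (196 total).
#' @param primers named integer vector: number of primers per marker system.
#' @param bands_per_primer integer length-2 range; each primer's band count
#'   is drawn uniformly from it.
#' @param divergence Balding-Nichols F, strictly inside (0, 1).
#' @param ancestral_range length-2 interval inside (0, 1) from which each
#'   band's ancestral dominant-allele frequency is drawn uniformly.  Bounded
#'   away from 0/1 so panels are not quasi-monomorphic.
#' @param seed integer RNG seed; the simulation is bit-reproducible given it.
#' @param study_labels if `TRUE` and `n_pops <= 20`, label populations with
#'   the accession codes, subspecies, countries and climates of the published
#'   *Dactylis* accession panel, so that grouped analyses have the study's
#'   structure; otherwise generic labels are generated.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_pops = 20,
                       samples_per_pop = rep(c(10L, 9L), c(16L, 4L)),
                       primers = c(SSR = 21L, `IT-ISJ` = 15L),
                       bands_per_primer = c(3L, 13L),
                       divergence = 0.2,
                       ancestral_range = c(0.05, 0.95),
                       seed = 1L,
                       study_labels = TRUE) {
  stopifnot(n_pops >= 1, all(primers >= 1), length(bands_per_primer) == 2)
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  if (any(samples_per_pop < 1)) stop("all population sizes must be positive")
  if (!(divergence > 0 && divergence < 1))
    stop("'divergence' must lie strictly in (0, 1)")
  if (any(ancestral_range <= 0) || any(ancestral_range >= 1) ||
      ancestral_range[1] > ancestral_range[2])
    stop("'ancestral_range' must be an interval inside (0, 1)")
  if (any(bands_per_primer < 1) || bands_per_primer[1] > bands_per_primer[2])
    stop("'bands_per_primer' must be a positive increasing range")
  structure(list(n_pops = as.integer(n_pops),
                 samples_per_pop = samples_per_pop,
                 primers = primers,
                 bands_per_primer = as.integer(bands_per_primer),
                 divergence = divergence,
                 ancestral_range = ancestral_range,
                 seed = as.integer(seed),
                 study_labels = isTRUE(study_labels)),
            class = "sim_config")
}

# dominant phenotype of a diploid under HWE: band shows unless both copies
# carry the null allele
presence_prob <- function(p) 1 - (1 - p)^2

sample_presence <- function(p, n) stats::rbinom(n, 1L, presence_prob(p))

#' Simulate a band matrix with known truth
#'
#' For each band, an ancestral dominant-allele frequency p0 is drawn
#' uniformly from `ancestral_range`; each population's frequency p is then
#' drawn from the Balding-Nichols Beta distribution with mean p0 and variance
#' `F * p0 * (1 - p0)` (shape parameters `p0(1-F)/F` and `(1-p0)(1-F)/F`).
#' Each diploid individual shows the band with probability `1 - (1 - p)^2`,
#' the dominant phenotype under Hardy-Weinberg equilibrium.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return A list of class `"band_sim"` with elements
#'   \describe{
#'     \item{matrix}{the simulated [band_matrix()];}
#'     \item{metadata}{sample metadata `data.frame` (sample_id, accession,
#'       subspecies, country, range, climate, population);}
#'     \item{truth}{list with `p0` (named ancestral frequencies), `p`
#'       (populations x bands matrix of true frequencies) and `divergence`.}
#'   }
#' @export
simulate_band_matrix <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(if (is.null(seed)) cfg$seed else as.integer(seed))
  F <- cfg$divergence
  n_primer <- sum(cfg$primers)
  primer_sys <- rep(names(cfg$primers), cfg$primers)
  primer_ids <- sprintf("%s_p%02d", gsub("[^A-Za-z0-9]", "", primer_sys),
                        stats::ave(seq_len(n_primer), primer_sys,
                                   FUN = seq_along))
  nb <- sample(cfg$bands_per_primer[1]:cfg$bands_per_primer[2], n_primer,
               replace = TRUE)
  band_primer <- rep(primer_ids, nb)
  band_ids <- paste0(band_primer, "_b", unlist(lapply(nb, seq_len)))
  names(band_primer) <- band_ids
  n_bands <- length(band_ids)

  p0 <- stats::runif(n_bands, cfg$ancestral_range[1], cfg$ancestral_range[2])
  names(p0) <- band_ids
  # Balding-Nichols: Beta(p0(1-F)/F, (1-p0)(1-F)/F) per population and band
  p <- matrix(stats::rbeta(cfg$n_pops * n_bands,
                           rep(p0, each = cfg$n_pops) * (1 - F) / F,
                           rep(1 - p0, each = cfg$n_pops) * (1 - F) / F),
              nrow = cfg$n_pops,
              dimnames = list(sprintf("pop%02d", seq_len(cfg$n_pops)),
                              band_ids))

  pop_of <- rep(seq_len(cfg$n_pops), cfg$samples_per_pop)
  n_ind <- length(pop_of)
  pres <- matrix(stats::rbinom(n_ind * n_bands, 1L,
                               presence_prob(p[pop_of, , drop = FALSE])),
                 nrow = n_ind)
  labels <- sim_population_labels(cfg)
  sample_id <- sprintf("%s_i%02d", labels$accession[pop_of],
                       stats::ave(pop_of, pop_of, FUN = seq_along))
  dimnames(pres) <- list(sample_id, band_ids)

  md <- data.frame(sample_id = sample_id,
                   accession = labels$accession[pop_of],
                   subspecies = labels$subspecies[pop_of],
                   country = labels$country[pop_of],
                   range = labels$range[pop_of],
                   climate = labels$climate[pop_of],
                   population = rownames(p)[pop_of],
                   stringsAsFactors = FALSE)
  structure(list(matrix = band_matrix(pres, band_primer,
                                      stats::setNames(primer_sys, primer_ids)),
                 metadata = md,
                 truth = list(p0 = p0, p = p, divergence = F)),
            class = "band_sim")
}

sim_population_labels <- function(cfg) {
  n <- cfg$n_pops
  if (cfg$study_labels && n <= 20) {
    acc <- published_summary("accessions")
    acc <- acc[seq_len(n), ]
    list(accession = acc$accession, subspecies = acc$subspecies,
         country = acc$country, range = acc$range, climate = acc$climate)
  } else {
    list(accession = sprintf("ACC%02d", seq_len(n)),
         subspecies = sprintf("ssp%02d", (seq_len(n) - 1L) %% max(1L, n %/% 2L) + 1L),
         country = sprintf("country%02d", seq_len(n)),
         range = rep("synthetic", n),
         climate = rep("synthetic", n))
  }
}

#' @export
print.band_sim <- function(x, ...) {
  cat(sprintf("band_sim: %d samples, %d bands, %d populations, F = %g\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              nrow(x$truth$p), x$truth$divergence))
  invisible(x)
}

#' Write the three simulator output files plus a truth table
#'
#' @param sim a `"band_sim"` from [simulate_band_matrix()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.  Files: `band_matrix.tsv`,
#'   `primer_systems.tsv`, `metadata.tsv`, `truth.tsv`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_band_matrix(sim$matrix, file.path(dir, "band_matrix.tsv"),
                    file.path(dir, "primer_systems.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(band = colnames(sim$truth$p),
                      p0 = sim$truth$p0[colnames(sim$truth$p)],
                      t(sim$truth$p), check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
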