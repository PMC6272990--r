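#' Pipeline configuration
#'
#' Exactly one of `input` (paths to an existing band matrix, primer-system
#' table and metadata) or `simulate` (a [sim_config()]) must be given.  The
#' global `seed` drives every stochastic stage: the simulator uses `seed`,
#' the tree bootstrap `seed + 1`, the AMOVA permutations `seed + 2`.
#'
#' @param input `NULL`, or a list with paths `matrix`, `system`, `metadata`.
#' @param simulate `NULL`, or a [sim_config()].
#' @param diversity_groups metadata column used for the diversity report.
#' @param amova_groups metadata column used for the overall AMOVA.
#' @param pic_mode PIC reading, see [pic_primer()].
#' @param freq_method allele-frequency estimator, see
#'   [dominant_allele_freq()].
#' @param bootstrap_reps tree bootstrap replicates.
#' @param amova_perms AMOVA permutations.
#' @param seed global integer seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            diversity_groups = "subspecies",
                            amova_groups = "accession",
                            pic_mode = "pattern", freq_method = "sqrt",
                            bootstrap_reps = 200, amova_perms = 999,
                            seed = 1L) {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' and 'simulate' must be given")
  if (!is.null(input) &&
      !all(c("matrix", "system", "metadata") %in% names(input)))
    stop("'input' needs paths 'matrix', 'system' and 'metadata'")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(input = input, simulate = simulate,
                 diversity_groups = diversity_groups,
                 amova_groups = amova_groups, pic_mode = pic_mode,
                 freq_method = freq_method,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 amova_perms = as.integer(amova_perms),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full dominant-marker analysis pipeline
#'
#' Loads (or simulates) a band matrix plus metadata and writes the report
#' bundle to `out_dir`: `table1.tsv` (per-primer polymorphism and PIC),
#' `table2.tsv` (per-system efficiency), `table3.tsv` (grouped diversity
#' with the It/Is/S' partition), `table4.tsv` (AMOVA, including
#' per-subspecies by-country runs where a subspecies spans several
#' countries), `tree.nwk` (bootstrap-annotated NJ tree), `distances.tsv`
#' (Dice dissimilarities), and `run_log.txt`.  Any stage failure aborts with
#' a stage-named error and removes the partially written bundle.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`matrix`,
#'   `metadata`, `efficiency`, `diversity`, `tree`, `amova`, `files`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("table1.tsv", "table2.tsv", "table3.tsv",
                                "table4.tsv", "tree.nwk", "distances.tsv",
                                "run_log.txt"))
  names(files) <- c("table1", "table2", "table3", "table4", "tree",
                    "distances", "log")
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(key, writer) {
    writer(files[[key]])
    written <<- c(written, files[[key]])
  }
  tsv <- function(df) function(path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

  dat <- stage("load", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_band_matrix(cfg$simulate, seed = cfg$seed)
      list(m = sim$matrix, md = sim$metadata)
    } else {
      m <- read_band_matrix(cfg$input$matrix, cfg$input$system)
      list(m = m, md = read_sample_metadata(cfg$input$metadata, m))
    }
  })
  m <- dat$m; md <- dat$md
  grp_of <- function(col) stats::setNames(md[[col]], md$sample_id)

  eff <- stage("efficiency", efficiency_report(m, pic_mode = cfg$pic_mode))
  emit("table1", tsv(eff$per_primer))
  emit("table2", tsv(eff$per_system))

  div <- stage("diversity",
               group_diversity(m, grp_of(cfg$diversity_groups),
                               method = cfg$freq_method))
  t3 <- div$groups
  part <- data.frame(group = names(div$partition), n = NA, Na = NA, Ne = NA,
                     He = NA, I = unname(div$partition))
  emit("table3", tsv(rbind(t3, part)))

  tr <- stage("tree", {
    d <- dissimilarity_matrix(m)
    emit("distances", tsv(data.frame(sample = rownames(d), d,
                                     check.names = FALSE)))
    bootstrap_support(m, n_reps = cfg$bootstrap_reps, seed = cfg$seed + 1L)
  })
  emit("tree", function(path) write_newick(tr, path))

  am <- stage("amova", {
    overall <- amova_oneway(squared_euclidean(m), grp_of(cfg$amova_groups),
                            n_perm = cfg$amova_perms, seed = cfg$seed + 2L)
    runs <- list(overall = overall)
    acc2ssp <- unique(md[c("subspecies", "country")])
    multi <- names(which(table(acc2ssp$subspecies) > 1))
    for (ssp in multi) {
      runs[[ssp]] <- tryCatch(
        amova_by_country(m, md, ssp, n_perm = cfg$amova_perms,
                         seed = cfg$seed + 2L),
        error = function(e) NULL)
    }
    runs[!vapply(runs, is.null, TRUE)]
  })
  t4 <- do.call(rbind, lapply(names(am), function(nm) {
    tab <- am[[nm]]$table
    cbind(analysis = nm, tab,
          p = c(am[[nm]]$p_value, NA, NA)[seq_len(nrow(tab))])
  }))
  emit("table4", tsv(t4))

  stage("log", emit("log", function(path) {
    writeLines(c(
      sprintf("bandpop %s | R %s", as.character(utils::packageVersion("bandpop")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", cfg$seed),
      sprintf("samples: %d  bands: %d  primers: %d", nrow(m$values),
              ncol(m$values), length(m$primer_system)),
      sprintf("diversity grouping: %s (%d groups)", cfg$diversity_groups,
              length(unique(md[[cfg$diversity_groups]]))),
      sprintf("amova grouping: %s (%d groups)", cfg$amova_groups,
              length(unique(md[[cfg$amova_groups]]))),
      sprintf("pic mode: %s | freq method: %s", cfg$pic_mode,
              cfg$freq_method),
      sprintf("bootstrap replicates: %d | amova permutations: %d",
              cfg$bootstrap_reps, cfg$amova_perms)), path)
  }))

  invisible(list(matrix = m, metadata = md, efficiency = eff,
                 diversity = div, tree = tr, amova = am, files = files))
}
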