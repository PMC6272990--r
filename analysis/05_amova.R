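#!/usr/bin/env Rscript
# Step 5 — one-way AMOVA on squared Euclidean (Hamming) distances: overall
# among/within accessions, plus by-country runs for every subspecies that
# spans several countries.  Writes table4.tsv.

library(bandpop)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 22L
m <- read_band_matrix("results/data/band_matrix.tsv",
                      "results/data/primer_systems.tsv")
md <- read_sample_metadata("results/data/metadata.tsv", m)
d2 <- squared_euclidean(m)

runs <- list(accessions = amova_oneway(
  d2, setNames(md$accession, md$sample_id), n_perm = 999, seed = seed))
for (ssp in unique(md$subspecies)) {
  r <- tryCatch(amova_by_country(m, md, ssp, n_perm = 999, seed = seed),
                error = function(e) NULL)
  if (!is.null(r)) runs[[paste0(ssp, "_countries")]] <- r
}

for (nm in names(runs)) {
  cat("\n==", nm, "==\n")
  print(runs[[nm]])
}

tab <- do.call(rbind, lapply(names(runs), function(nm) {
  t <- runs[[nm]]$table
  cbind(analysis = nm, t, p = c(runs[[nm]]$p_value, NA, NA)[seq_len(nrow(t))])
}))
write.table(tab, "results/table4.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\noverall among-accession share: %.1f%% (Phi = %.3f, p = %.3g)\n",
            runs$accessions$table$percent[1], runs$accessions$phi,
            runs$accessions$p_value))
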