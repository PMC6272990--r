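#!/usr/bin/env Rscript
# Step 4 — Dice dissimilarities, accession-level mean similarities, and the
# unweighted neighbor-joining tree of all individuals with band-bootstrap
# support.  Writes distances.tsv, group_similarity.tsv and tree.nwk.

library(bandpop)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 21L
m <- read_band_matrix("results/data/band_matrix.tsv",
                      "results/data/primer_systems.tsv")
md <- read_sample_metadata("results/data/metadata.tsv", m)

d <- dissimilarity_matrix(m)
write.table(data.frame(sample = rownames(d), d, check.names = FALSE),
            "results/distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

gs <- group_mean_similarity(m, setNames(md$subspecies, md$sample_id))
write.table(data.frame(group = rownames(gs), round(gs, 4),
                       check.names = FALSE),
            "results/group_similarity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("subspecies mean similarities span",
    sprintf("%.3f-%.3f\n", min(gs[upper.tri(gs)]), max(gs[upper.tri(gs)])))

tr <- bootstrap_support(m, n_reps = 500, seed = seed)
write_newick(tr, "results/tree.nwk")
sup <- suppressWarnings(as.integer(tr$node.label))
cat(sprintf("tree written; bootstrap support median %d%%, %d/%d edges >= 50%%\n",
            round(median(sup, na.rm = TRUE)), sum(sup >= 50, na.rm = TRUE),
            sum(!is.na(sup))))
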