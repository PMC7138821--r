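#!/usr/bin/env Rscript

# Stage 2 — representative accession selection.
#
# From the stage-1 panel: identity-by-state distances, principal
# coordinates (the "PCA of the IBS matrix", 5 axes), and for each called
# subpopulation the member closest to the group centroid among accessions
# with seed available. A few samples are marked unavailable to exercise the
# availability rule.
#
# Reads:  results/panel_genotypes.txt, results/calls.csv
# Writes: results/coordinates.csv, results/representatives.csv

library(panstruct)

g <- read_genotypes("results/panel_genotypes.txt", "simple_matrix")
calls <- read.csv("results/calls.csv", stringsAsFactors = FALSE)
stopifnot(identical(calls$sample_id, rownames(g)))

D <- ibs_distance(g)
coords <- suppressWarnings(principal_axes(D, n_axes = 5))
write.csv(data.frame(sample_id = rownames(coords), coords),
          "results/coordinates.csv", row.names = FALSE)

set.seed(7)
available <- runif(nrow(g)) > 0.1   # ~10% of accessions lack seed

groups <- setdiff(unique(calls$label),
                  c("admixed", "cA-adm", "XI-adm", "GJ-adm"))
reps <- vapply(sort(groups), function(gr)
  select_representative(coords, calls$label, gr, available), character(1))
rep_df <- data.frame(group = names(reps), representative = reps,
                     row.names = NULL)
write.csv(rep_df, "results/representatives.csv", row.names = FALSE)
cat("selected representatives:\n")
print(rep_df)
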