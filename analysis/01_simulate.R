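#!/usr/bin/env Rscript

# Generate the synthetic etoposide study: four dose conditions (UT, 2.5,
# 10, 25 uM analogues) of 500 cells each over 1,500 genes, with the
# planted arrest-depth continuum, the mitosis-to-G0 and mitotic-slip
# branches, three senotypes, graded pan-senescence/SASP/biosynthesis
# programs, and full ground truth. Writes a 10x-style matrix plus truth
# tables and the gene-set collections used downstream.

suppressPackageStartupMessages(library(senotyper))

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- continuum_params(seed = 1)
sim <- simulate_counts(params)

write_10x(sim$matrix, file.path(out, "counts_10x"))
write.csv(sim$cell_truth, file.path(out, "cell_truth.csv"),
          row.names = FALSE)
write.csv(sim$gene_truth, file.path(out, "gene_truth.csv"),
          row.names = FALSE)
yaml::write_yaml(
  params[setdiff(names(params), "extra_programs")],
  file.path(out, "params.yaml"))

sets <- planted_gene_sets(sim)
write_gmt(sets, file.path(out, "gene_sets.gmt"))

cat(sprintf(
  "simulated %d cells x %d genes: %d cycling, %d g0-path, %d slip-path;\n",
  ncol(sim$matrix), nrow(sim$matrix),
  sum(sim$cell_truth$branch == "cycling"),
  sum(sim$cell_truth$branch == "g0_path"),
  sum(sim$cell_truth$branch == "slip_path")))
print(table(dose = sim$cell_truth$dose,
            senotype = ifelse(is.na(sim$cell_truth$senotype), "none",
                              sim$cell_truth$senotype)))
cat("outputs under", out, "\n")
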