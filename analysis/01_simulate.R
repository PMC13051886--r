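#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream drivers: a
# miRNA cohort with 10 planted suppressed miRNAs, the regulated mRNA layer
# with its binding-site and interaction tables, a qPCR plate, and a
# single-cell cohort with rare Tc17/Treg programs (2% controls vs 4% cases).
# Everything is written as plain-text fixtures under results/inputs/.

suppressMessages(library(autoimmir))

seed <- 42
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, n_de = 10, de_direction = "down",
                  effect_size = 1, suppression = 1,
                  targets_per_mirna = 60, n_genes = 4000,
                  n_donors = 6, cells_per_donor = 150, n_genes_sc = 1000)

mir <- simulate_mirna_matrix(cfg)
write_expression_tsv(mir$matrix, file.path(out, "mirna_expression.tsv"))
write_tsv_table(mir$truth$de_features, file.path(out, "truth_mirna_de.tsv"))

tx <- simulate_regulated_transcriptome(cfg, mir$truth)
write_expression_tsv(tx$matrix, file.path(out, "gene_expression.tsv"))
write_tsv_table(tx$sites, file.path(out, "binding_sites.tsv"))
write_tsv_table(tx$interactions, file.path(out, "interactions.tsv"))
write_tsv_table(tx$truth$regulon, file.path(out, "truth_regulon.tsv"))

qtab <- simulate_qpcr(cfg, c(`miR-val-1` = 0.5, `miR-val-2` = 0.5))
write_tsv_table(qtab, file.path(out, "qpcr_ct.tsv"))

sc <- simulate_single_cell(cfg)
write_mtx_dir(sc$sce, file.path(out, "single_cell"))
write_tsv_table(sc$truth$donor_frequencies,
                file.path(out, "truth_donor_frequencies.tsv"))
write_gmt(cfg$signatures, file.path(out, "signatures.gmt"))

message("planted regulators: ",
        paste(unique(tx$truth$regulon$mirna), collapse = ", "))
message("cells simulated: ", ncol(sc$sce),
        " (Tc17 truth: ",
        sprintf("%.1f%%", 100 * mean(sc$truth$cell_labels == "Tc17")), ")")
message("inputs written under ", out)
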