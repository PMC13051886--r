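#!/usr/bin/env Rscript
# Bulk differential expression on the simulated inputs: the miRNA arm
# (top-400 filter, surrogate variables, moderated t, Storey q at 0.05) and
# the gene arm (quantile normalization, intensity floor 6, moderated t,
# q < 0.1 with |FC| > 1.5). Reads results/inputs/, writes results/bulk_de/.

suppressMessages(library(autoimmir))

inp <- "results/inputs"
out <- "results/bulk_de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

mirna <- read_expression_tsv(file.path(inp, "mirna_expression.tsv"))
mirna <- filter_top_expressed(mirna, min(400, nrow(mirna$values)))
sv <- estimate_surrogate_variables(mirna, seed = seed)
message("surrogate variables used: ", ncol(sv))
mirna_de <- moderated_t_test(mirna, covariates = sv)
write_de_tsv(mirna_de, file.path(out, "mirna_de.tsv"))
mirna_hits <- call_de(mirna_de, q_max = 0.05, min_abs_fc = 1)
message("DE-miRNAs at q < 0.05: ", length(mirna_hits$all),
        " (", length(mirna_hits$down), " down)")

genes <- read_expression_tsv(file.path(inp, "gene_expression.tsv"))
genes <- filter_low_intensity(quantile_normalize(genes), 6)
message("genes kept after intensity filter: ", nrow(genes$values))
gene_de <- moderated_t_test(genes)
write_de_tsv(gene_de, file.path(out, "gene_de.tsv"))
gene_hits <- call_de(gene_de, q_max = 0.1, min_abs_fc = 1.5)
message("DEGs (q < 0.1, |FC| > 1.5): ", length(gene_hits$all),
        " (", length(gene_hits$up), " up / ", length(gene_hits$down), " down)")

md <- classical_mds(genes, dims = 2, top_features = 500)
write_tsv_table(
  data.frame(sample = rownames(md$coords), md$coords,
             group = genes$samples$group),
  file.path(out, "gene_mds.tsv")
)

hit_lists <- data.frame(
  feature = c(mirna_hits$up, mirna_hits$down, gene_hits$up, gene_hits$down),
  layer = c(rep("mirna", length(mirna_hits$all)),
            rep("gene", length(gene_hits$all))),
  direction = c(rep("up", length(mirna_hits$up)),
                rep("down", length(mirna_hits$down)),
                rep("up", length(gene_hits$up)),
                rep("down", length(gene_hits$down)))
)
write_tsv_table(hit_lists, file.path(out, "de_calls.tsv"))
message("tables written under ", out)
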