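#!/usr/bin/env Rscript
# Binding-site enrichment and miRNA activity inference: Fisher tests per
# motif and direction (adjusted p < 0.05), intersection with the observed
# DE-miRNAs, network assembly against the interaction table, and a recovery
# scorecard against the planted regulon. GSEA of each planted regulator's
# target set over the gene t-ranking cross-checks the de-repression signal.

suppressMessages(library(autoimmir))

inp <- "results/inputs"
de_dir <- "results/bulk_de"
out <- "results/site_activity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

sites <- read_tsv_table(file.path(inp, "binding_sites.tsv"))
interactions <- read_tsv_table(file.path(inp, "interactions.tsv"))
regulon <- read_tsv_table(file.path(inp, "truth_regulon.tsv"))
calls <- read_tsv_table(file.path(de_dir, "de_calls.tsv"))
gene_tab <- read_tsv_table(file.path(de_dir, "gene_de.tsv"))

gene_de <- structure(list(table = gene_tab), class = "DEResult")
universe <- gene_tab$feature
gh <- list(up = calls$feature[calls$layer == "gene" & calls$direction == "up"],
           down = calls$feature[calls$layer == "gene" & calls$direction == "down"])

rows <- site_enrichment(sites, gh$up, gh$down, universe, adj_p_max = 0.05)
write_tsv_table(rows, file.path(out, "site_enrichment.tsv"))
message("significant motifs (adj p < 0.05): ", nrow(rows))

de_mirnas <- calls[calls$layer == "mirna", c("feature", "direction")]
names(de_mirnas) <- c("mirna", "direction")
influential <- intersect_influential(rows, de_mirnas)
write_tsv_table(influential, file.path(out, "influential_mirnas.tsv"))

planted <- unique(regulon$mirna)
recovered <- unique(unlist(strsplit(
  influential$mirnas[influential$estimated_activity == "Downregulated"], ",")))
message("planted suppressed miRNAs recovered: ",
        length(intersect(recovered, planted)), " / ", length(planted))

target_sets <- split(regulon$gene, regulon$mirna)
gsea <- gsea_preranked(setNames(gene_tab$t, gene_tab$feature), target_sets,
                       n_perm = 1000, seed = seed)
write_tsv_table(gsea, file.path(out, "gsea_target_sets.tsv"))
message("target sets with positive ES at adj p < 0.1: ",
        sum(gsea$ES > 0 & gsea$adj_p < 0.1), " / ", nrow(gsea))

net <- build_network(influential, interactions, gene_de,
                     pathways = target_sets,
                     min_set_size = min(8, min(lengths(target_sets))))
write_network(net, file.path(out, "network_edges.tsv"),
              file.path(out, "network.graphml"))
message("network edges: ", nrow(net$edges), " (",
        sum(net$edges$evidence == "validated"), " validated)")

scorecard <- data.frame(
  n_planted = length(planted),
  n_recovered = length(intersect(recovered, planted)),
  n_false = length(setdiff(recovered, planted)),
  network_edges = nrow(net$edges)
)
write_tsv_table(scorecard, file.path(out, "recovery_scorecard.tsv"))
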