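#!/usr/bin/env Rscript
# qPCR validation arithmetic on the simulated plate: standard-curve
# efficiencies, housekeeping stability on the miRNA matrix, 2^-ddCt
# quantification of the two planted half-fold miRNAs, Welch tests on dCt,
# and the miRNA-target dCt correlation.

suppressMessages(library(autoimmir))

inp <- "results/inputs"
out <- "results/qpcr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_tsv_table(file.path(inp, "qpcr_ct.tsv"))
mirna <- read_expression_tsv(file.path(inp, "mirna_expression.tsv"))

hk <- select_housekeeping(mirna)
write_tsv_table(utils::head(hk, 20), file.path(out, "housekeeping_ranking.tsv"))
message("selected normalizer: ", hk$feature[hk$selected],
        sprintf(" (CV = %.3f)", hk$cv[hk$selected]))

assays <- setdiff(unique(tab$assay), "HK")
eff <- do.call(rbind, lapply(c(assays, "HK"), function(a) {
  f <- fit_efficiency(tab, a)
  data.frame(assay = a, slope = f$slope, r_squared = f$r_squared,
             efficiency_percent = f$efficiency_percent, pass = f$pass)
}))
write_tsv_table(eff, file.path(out, "efficiencies.tsv"))
message("efficiencies: ", paste(sprintf("%s %.1f%%", eff$assay,
                                        eff$efficiency_percent), collapse = ", "))

rel_all <- list()
tests <- list()
for (a in assays) {
  rel <- ddct(tab, a, "HK")
  rel$assay <- a
  rel_all[[a]] <- rel
  gt <- group_test(rel$dct, rel$group)
  tests[[a]] <- data.frame(
    assay = a, mean_case_fold = mean(rel$fold[rel$group == "case"]),
    welch_t = gt$t, welch_df = gt$df, welch_p = gt$p,
    shapiro_flag = gt$normality_flag
  )
  message(sprintf("%s: mean case fold %.2f, Welch p %.3g", a,
                  mean(rel$fold[rel$group == "case"]), gt$p))
}
write_tsv_table(do.call(rbind, rel_all), file.path(out, "relative_expression.tsv"))
write_tsv_table(do.call(rbind, tests), file.path(out, "group_tests.tsv"))

# the two planted assays share the same fold: their dCt series correlate
r1 <- rel_all[[assays[1]]]
r2 <- rel_all[[assays[2]]]
pc <- pair_correlation(r1$dct, r2$dct[match(r1$sample, r2$sample)])
write_tsv_table(data.frame(pair = paste(assays[1], assays[2], sep = " vs "),
                           r = pc$r, p = pc$p),
                file.path(out, "pair_correlation.tsv"))
message(sprintf("dCt correlation between the two assays: r = %.2f (p = %.3g)",
                pc$r, pc$p))
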