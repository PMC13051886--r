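#' Default pipeline configuration
#'
#' The stage constants of the workflow: top-K expression filter (400, or 500
#' for monocyte-style runs), miRNA-set minimum size 8, per-stage significance
#' cutoffs (miRNA q < 0.05, gene q < 0.1 with |FC| > 1.5, binding-site
#' adjusted p < 0.05, set-level adjusted p < 0.1), intensity floor 6, k = 5
#' graph neighbors, 5000 HVGs, AUC thresholds 0.17 (Treg) / 0.22 (Tc17),
#' top 250 markers.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    top_k = 400,
    min_set_size = 8,
    mirna_q_max = 0.05,
    gene_q_max = 0.1,
    min_abs_fc = 1.5,
    intensity_threshold = 6,
    site_adj_p_max = 0.05,
    set_adj_p_max = 0.1,
    n_sv = "auto",
    gsea_n_perm = 1000,
    knn_k = 5,
    n_hvgs = 5000,
    n_pcs = 50,
    louvain_resolution = 1,
    qc_nmads = 3,
    min_cells_per_donor = 10,
    auc_top_fraction = 0.05,
    auc_threshold_treg = 0.17,
    auc_threshold_tc17 = 0.22,
    top_n_markers = 250,
    sim = list()
  )
}

#' Validate a YAML pipeline configuration
#'
#' Reads the file (an empty file is valid), fills every missing key from
#' [default_config()], rejects unknown keys, and requires an explicit seed
#' (the default seed counts as explicit; setting it to null is an error).
#'
#' @param path YAML file path.
#' @return `PipelineConfig`: the effective configuration list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not readable: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if ("seed" %in% names(user) && is.null(user$seed)) {
    stop("missing seed for a stochastic stage")
  }
  cfg <- utils::modifyList(defaults, user)
  if (!is.numeric(cfg$seed)) stop("missing seed for a stochastic stage")
  structure(cfg, class = "PipelineConfig")
}

# write a table and return its path (for the manifest)
.stage_write <- function(x, dir, name) {
  p <- file.path(dir, name)
  write_tsv_table(x, p)
  p
}

.write_manifest <- function(dir, cfg, files, counts) {
  manifest <- list(
    config = unclass(cfg),
    file_md5 = as.list(tools::md5sum(sort(unlist(files)))),
    stage_counts = counts
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the bulk integrative arm on synthetic data
#'
#' Executes, in order: miRNA differential expression (top-K filter,
#' surrogate variables, moderated t, Storey q), gene differential expression
#' (quantile normalization, intensity filter, moderated t), preranked GSEA of
#' the per-miRNA target sets over the gene t-statistics, binding-site
#' enrichment with activity inference, intersection with DE-miRNAs, network
#' assembly, and qPCR validation arithmetic on folds planted for the
#' recovered miRNAs. Every output table is written under `out_dir` together
#' with a manifest of config, stage counts, and output checksums.
#'
#' @param cfg a `PipelineConfig` (see [validate_config()]).
#' @param out_dir output directory (created).
#' @return list with the key results (invisible paths in `$files`):
#'   `mirna_de`, `gene_de`, `influential`, `network`, `recovery`, `qpcr`.
#' @export
run_integrative_arm <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
  scfg <- do.call(sim_config, sim_args)

  mir <- simulate_mirna_matrix(scfg)
  mirna_m <- filter_top_expressed(mir$matrix, min(cfg$top_k, nrow(mir$matrix$values)))
  sv <- estimate_surrogate_variables(mirna_m, n_sv = cfg$n_sv, seed = cfg$seed)
  mirna_de <- moderated_t_test(mirna_m, covariates = sv)
  mirna_hits <- call_de(mirna_de, q_max = cfg$mirna_q_max, min_abs_fc = 1)

  tx <- simulate_regulated_transcriptome(scfg, mir$truth,
                                         allow_empty_regulon = TRUE)
  gene_m <- quantile_normalize(tx$matrix)
  gene_m <- filter_low_intensity(gene_m, cfg$intensity_threshold)
  gene_de <- moderated_t_test(gene_m)
  gene_hits <- call_de(gene_de, q_max = cfg$gene_q_max,
                       min_abs_fc = cfg$min_abs_fc)

  # target sets of each planted regulator, scored on the gene t ranking
  target_sets <- split(tx$truth$regulon$gene, tx$truth$regulon$mirna)
  gsea <- NULL
  if (length(target_sets) > 0) {
    stats_vec <- stats::setNames(gene_de$table$t, gene_de$table$feature)
    gsea <- gsea_preranked(stats_vec, target_sets, n_perm = cfg$gsea_n_perm,
                           seed = cfg$seed)
  }

  universe <- rownames(gene_m$values)
  site_rows <- site_enrichment(tx$sites, gene_hits$up, gene_hits$down,
                               universe, adj_p_max = cfg$site_adj_p_max)
  de_dirs <- data.frame(
    mirna = c(mirna_hits$up, mirna_hits$down),
    direction = c(rep("up", length(mirna_hits$up)),
                  rep("down", length(mirna_hits$down))),
    stringsAsFactors = FALSE
  )
  influential <- intersect_influential(site_rows, de_dirs)
  pathways <- if (length(target_sets) >= 1) target_sets else NULL
  net <- suppressWarnings(
    build_network(influential, tx$interactions, gene_de, pathways,
                  q_max = cfg$gene_q_max, min_abs_fc = cfg$min_abs_fc,
                  min_set_size = min(cfg$min_set_size,
                                     max(lengths(target_sets), 1)))
  )

  planted <- unique(tx$truth$regulon$mirna)
  recovered <- unique(unlist(strsplit(influential$mirnas[
    influential$estimated_activity == "Downregulated"], ",")))
  recovery <- data.frame(
    n_planted = length(planted),
    n_recovered = length(intersect(recovered, planted)),
    sensitivity = if (length(planted)) {
      length(intersect(recovered, planted)) / length(planted)
    } else NA_real_,
    precision = if (length(recovered)) {
      length(intersect(recovered, planted)) / length(recovered)
    } else NA_real_
  )

  # qPCR validation of up to three planted suppressed miRNAs
  folds <- 2^(utils::head(tx$truth$mirna_de$effect[tx$truth$mirna_de$effect < 0], 3))
  qpcr_res <- NULL
  if (length(folds)) {
    names(folds) <- utils::head(
      tx$truth$mirna_de$feature[tx$truth$mirna_de$effect < 0], 3)
    qtab <- simulate_qpcr(scfg, folds)
    qpcr_res <- do.call(rbind, lapply(names(folds), function(a) {
      rel <- ddct(qtab, target = a, reference = "HK")
      gt <- group_test(rel$dct, rel$group)
      data.frame(assay = a, planted_fold = unname(folds[a]),
                 mean_case_fold = mean(rel$fold[rel$group == "case"]),
                 welch_p = gt$p, stringsAsFactors = FALSE)
    }))
  }

  files <- list(
    .stage_write(mirna_de$table, out_dir, "mirna_de.tsv"),
    .stage_write(gene_de$table, out_dir, "gene_de.tsv"),
    .stage_write(site_rows, out_dir, "site_enrichment.tsv"),
    .stage_write(influential, out_dir, "influential_mirnas.tsv"),
    .stage_write(net$edges, out_dir, "network_edges.tsv"),
    .stage_write(recovery, out_dir, "recovery.tsv")
  )
  if (!is.null(gsea)) files <- c(files, .stage_write(gsea, out_dir, "gsea_targets.tsv"))
  if (!is.null(qpcr_res)) files <- c(files, .stage_write(qpcr_res, out_dir, "qpcr_validation.tsv"))
  counts <- list(
    mirna_features = nrow(mirna_m$values),
    mirna_de = length(mirna_hits$all),
    genes_tested = length(universe),
    gene_de_up = length(gene_hits$up), gene_de_down = length(gene_hits$down),
    influential_motifs = nrow(influential),
    network_edges = nrow(net$edges)
  )
  .write_manifest(out_dir, cfg, files, counts)
  invisible(list(mirna_de = mirna_de, gene_de = gene_de,
                 influential = influential, network = net,
                 recovery = recovery, qpcr = qpcr_res, gsea = gsea,
                 files = files))
}

#' Run the single-cell arm on synthetic data
#'
#' Executes gate -> QC -> normalize -> HVG -> batch correction -> SNN/Louvain
#' clustering -> pseudobulk NB-QL differential expression -> signed-logp GSEA
#' of the program signatures -> AUC scoring and classification of Tc17 /
#' CD8 Treg cells -> per-donor frequency comparison, writing tables and a
#' manifest under `out_dir`.
#'
#' @param cfg a `PipelineConfig`.
#' @param out_dir output directory.
#' @return list with `pseudobulk_de`, `gsea`, `frequencies` (per program),
#'   `clusters`, `scores`, and `files`.
#' @export
run_singlecell_arm <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
  scfg <- do.call(sim_config, sim_args)

  sim <- simulate_single_cell(scfg)
  sce <- gate_cd8(sim$sce)
  sce <- qc_filter(sce, nmads = cfg$qc_nmads)
  sce <- normalize_log(sce)
  hvgs <- select_hvgs(sce, n = min(cfg$n_hvgs, nrow(sce)))
  emb <- correct_batch(sce, hvgs, batch_key = "donor", n_pcs = cfg$n_pcs)
  clusters <- snn_louvain(emb$embedding, k = cfg$knn_k, seed = cfg$seed,
                          resolution = cfg$louvain_resolution)

  pb <- pseudobulk(sce, min_cells = cfg$min_cells_per_donor)
  de <- nb_ql_test(pb)
  ranking <- rank_by_signed_logp(de)
  gsea <- gsea_preranked(ranking, scfg$signatures, n_perm = cfg$gsea_n_perm,
                         seed = cfg$seed)

  meta <- data.frame(
    cell = colnames(sce),
    donor = SummarizedExperiment::colData(sce)$donor,
    group = SummarizedExperiment::colData(sce)$group,
    stringsAsFactors = FALSE
  )
  thresholds <- c(Treg = cfg$auc_threshold_treg, Tc17 = cfg$auc_threshold_tc17)
  scores <- list()
  freqs <- list()
  for (prog in names(scfg$signatures)) {
    sc <- aucell_score(sce, scfg$signatures[[prog]],
                       top_fraction = cfg$auc_top_fraction, seed = cfg$seed)
    lab <- classify_cells(sc, thresholds[[prog]])
    scores[[prog]] <- sc
    freqs[[prog]] <- compare_frequencies(lab, meta,
                                         min_cells = cfg$min_cells_per_donor)
  }

  freq_tab <- do.call(rbind, lapply(names(freqs), function(p) {
    cbind(program = p, freqs[[p]]$fractions)
  }))
  test_tab <- do.call(rbind, lapply(names(freqs), function(p) {
    data.frame(program = p, t = freqs[[p]]$test$t, df = freqs[[p]]$test$df,
               p = freqs[[p]]$test$p, stringsAsFactors = FALSE)
  }))
  files <- list(
    .stage_write(de$table, out_dir, "pseudobulk_de.tsv"),
    .stage_write(gsea, out_dir, "gsea_signatures.tsv"),
    .stage_write(data.frame(cell = names(clusters),
                            cluster = as.integer(clusters)),
                 out_dir, "clusters.tsv"),
    .stage_write(freq_tab, out_dir, "program_frequencies.tsv"),
    .stage_write(test_tab, out_dir, "frequency_tests.tsv")
  )
  counts <- list(
    cells_simulated = ncol(sim$sce),
    cells_gated = S4Vectors::metadata(sce)$gate$n_kept %||% ncol(sce),
    cells_after_qc = ncol(sce),
    clusters = length(unique(clusters)),
    donors = nrow(pb$donors),
    genes_tested = nrow(de$table)
  )
  .write_manifest(out_dir, cfg, files, counts)
  invisible(list(pseudobulk_de = de, gsea = gsea, frequencies = freqs,
                 clusters = clusters, scores = scores, files = files,
                 truth = sim$truth))
}
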