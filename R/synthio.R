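#' Default Tc17 and CD8 Treg signature gene lists
#'
#' The literature-curated marker lists used throughout the single-cell arm:
#' CD8 Tregs are marked by a FOXP3/IKZF2/CTLA4-type program and Tc17 cells by
#' a RORC/IL17A/IL23R-type program.
#'
#' @return Named list with elements `Treg` and `Tc17`.
#' @export
default_signatures <- function() {
  list(
    Treg = c("FOXP3", "IKZF2", "PRDM1", "CTLA4", "PDCD1", "LAG3", "IL10",
             "TGFB1", "IL2RA", "ENTPD1", "NT5E", "IKZF4", "GZMB", "ENPP1"),
    Tc17 = c("RORC", "BATF", "STAT3", "IL17A", "IL17F", "IL22", "IL23R", "KLRB1")
  )
}

#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator; there is no implicit
#' randomness anywhere. Defaults describe the study conditions the generators
#' emulate: a two-arm case/control cohort profiled on log2-scale arrays
#' (Gaussian noise, additive per-batch shifts), an mRNA layer in which targets
#' of suppressed miRNAs are up-shifted, negative-binomial single-cell counts
#' from multiple donors carrying rare signature-bearing subpopulations, and
#' dilution-series qPCR standards.
#'
#' @param seed integer seed (mandatory).
#' @param n_features number of miRNA features.
#' @param n_samples_per_group bulk samples per group.
#' @param n_de number of planted differentially expressed miRNAs.
#' @param effect_size planted log2 effect (case minus control).
#' @param de_direction direction of planted effects: "both" alternates signs,
#'   "down"/"up" force one sign.
#' @param batch_count,batch_sd number of batches and SD of the per-batch
#'   per-feature additive shifts.
#' @param noise_sd residual Gaussian SD on the log2 scale.
#' @param baseline_mean,baseline_sd distribution of feature baselines (log2).
#' @param n_genes,targets_per_mirna,suppression,n_de_genes mRNA layer: gene
#'   universe size, targets per suppressed miRNA, suppression strength
#'   (log2 target up-shift per unit of miRNA down-shift), and number of
#'   miRNA-independent planted DE genes.
#' @param bg_motif_density fraction of non-target genes decorated with each
#'   motif as background.
#' @param n_decoy_edges predicted decoy interactions added to the table.
#' @param n_donors donors per group (single cell).
#' @param cells_per_donor cells simulated per donor.
#' @param n_genes_sc single-cell gene universe size (includes the lineage,
#'   mitochondrial, and signature genes).
#' @param nb_mean median-scale NB mean per gene (gene means are log-normal
#'   around this value).
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param program_frequencies named list with per-group named vectors of
#'   Tc17/Treg frequencies; the remainder is "none".
#' @param signature_fold multiplicative fold applied to signature genes in
#'   cells of that program.
#' @param signatures named list of signature gene vectors.
#' @param gene_universe optional explicit single-cell gene universe; by
#'   default one is constructed containing the lineage, mitochondrial, and
#'   signature genes. Signature genes missing from an explicit universe are
#'   an error.
#' @param qpcr_n_per_group,qpcr_noise_sd,qpcr_replicates unknown-sample qPCR
#'   design.
#' @param qpcr_slope,qpcr_intercept,qpcr_dilutions,qpcr_std_noise_sd standard
#'   curve design (the default slope -3.3219 corresponds to 100% efficiency).
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_features = 400,
                       n_samples_per_group = 10,
                       n_de = 20,
                       effect_size = 1,
                       de_direction = c("both", "down", "up"),
                       batch_count = 2,
                       batch_sd = 0.5,
                       noise_sd = 0.3,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       n_genes = 4000,
                       targets_per_mirna = 60,
                       suppression = 1,
                       n_de_genes = 100,
                       bg_motif_density = 0.05,
                       n_decoy_edges = 2000,
                       n_donors = 12,
                       cells_per_donor = 400,
                       n_genes_sc = 2000,
                       nb_mean = 0.5,
                       nb_dispersion = 0.5,
                       program_frequencies = list(
                         control = c(Tc17 = 0.02, Treg = 0.02),
                         case = c(Tc17 = 0.04, Treg = 0.04)
                       ),
                       signature_fold = 4,
                       signatures = default_signatures(),
                       gene_universe = NULL,
                       qpcr_n_per_group = 10,
                       qpcr_noise_sd = 0.2,
                       qpcr_replicates = 3,
                       qpcr_slope = -3.3219,
                       qpcr_intercept = 24,
                       qpcr_dilutions = 10^(0:-4),
                       qpcr_std_noise_sd = 0) {
  if (missing(seed)) stop("`seed` is mandatory: no implicit randomness")
  de_direction <- match.arg(de_direction)
  cfg <- as.list(environment())
  counts <- c("n_features", "n_samples_per_group", "batch_count", "n_genes",
              "targets_per_mirna", "n_donors", "cells_per_donor", "n_genes_sc",
              "qpcr_n_per_group", "qpcr_replicates")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) stop("`", nm, "` must be a positive count")
  }
  if (cfg$n_de < 0 || cfg$n_de > cfg$n_features) {
    stop("invalid config: n_de must lie in [0, n_features]")
  }
  if (cfg$nb_dispersion < 0 || cfg$noise_sd < 0 || cfg$batch_sd < 0) {
    stop("dispersions and SDs must be non-negative")
  }
  for (g in names(cfg$program_frequencies)) {
    f <- cfg$program_frequencies[[g]]
    if (any(f < 0) || sum(f) > 1) {
      stop("program frequencies must be in [0,1] and sum (with 'none') to 1")
    }
  }
  structure(cfg, class = "SimConfig")
}

# sample annotation table for a two-group bulk design
.bulk_samples <- function(cfg, prefix = "S") {
  n <- cfg$n_samples_per_group
  data.frame(
    sample = sprintf("%s%02d", prefix, seq_len(2 * n)),
    group = rep(c("control", "case"), each = n),
    batch = sprintf("b%d", ((seq_len(2 * n) - 1) %% cfg$batch_count) + 1),
    donor = sprintf("%sD%02d", prefix, seq_len(2 * n)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-group miRNA log2 expression matrix with planted truth
#'
#' Gaussian log2-scale intensities with feature baselines, additive per-batch
#' per-feature shifts (shared within batch, so surrogate-variable recovery is
#' meaningful), and `n_de` planted features shifted by `effect_size` in the
#' case group.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `matrix` (an [expression_matrix()]) and `truth`
#'   (class `SyntheticTruth`: `de_features` data.frame of feature/effect,
#'   `batch_effects` feature x batch matrix).
#' @export
simulate_mirna_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    feats <- sprintf("miR-%04d", seq_len(cfg$n_features))
    samples <- .bulk_samples(cfg)
    n_smp <- nrow(samples)
    baseline <- stats::rnorm(cfg$n_features, cfg$baseline_mean, cfg$baseline_sd)
    vals <- matrix(baseline, cfg$n_features, n_smp) +
      matrix(stats::rnorm(cfg$n_features * n_smp, 0, cfg$noise_sd),
             cfg$n_features, n_smp)
    dimnames(vals) <- list(feats, samples$sample)

    batches <- sort(unique(samples$batch))
    batch_eff <- matrix(stats::rnorm(cfg$n_features * length(batches), 0, cfg$batch_sd),
                        cfg$n_features, length(batches),
                        dimnames = list(feats, batches))
    vals <- vals + batch_eff[, samples$batch, drop = FALSE]

    de <- data.frame(feature = character(0), effect = numeric(0))
    if (cfg$n_de > 0) {
      idx <- sample.int(cfg$n_features, cfg$n_de)
      sign_vec <- switch(cfg$de_direction,
        both = rep_len(c(1, -1), cfg$n_de),
        down = rep(-1, cfg$n_de),
        up   = rep(1, cfg$n_de)
      )
      eff <- sign_vec * cfg$effect_size
      vals[idx, samples$group == "case"] <-
        vals[idx, samples$group == "case"] + eff
      de <- data.frame(feature = feats[idx], effect = eff,
                       stringsAsFactors = FALSE)
    }
    truth <- structure(
      list(de_features = de, batch_effects = batch_eff),
      class = "SyntheticTruth"
    )
    list(matrix = expression_matrix(vals, samples), truth = truth)
  })
}

# deterministic unique 7-mer motifs over the RNA alphabet, one per miRNA
.make_motifs <- function(mirnas) {
  alph <- c("A", "C", "G", "U")
  motifs <- character(0)
  out <- character(length(mirnas))
  for (i in seq_along(mirnas)) {
    repeat {
      m <- paste(sample(alph, 7, replace = TRUE), collapse = "")
      if (!m %in% motifs) break
    }
    motifs <- c(motifs, m)
    out[i] <- m
  }
  names(out) <- mirnas
  out
}

#' Simulate an mRNA layer regulated by planted suppressed miRNAs
#'
#' Targets of each planted down-regulated miRNA gain
#' `suppression * |miRNA effect|` log2 units in cases (the de-repression
#' premise: less miRNA, more target). The binding-site table carries each
#' regulator's motif in all of its targets plus background decoration of
#' non-targets at `bg_motif_density`; every decoy miRNA's motif is planted at
#' background density only. The interaction table lists planted edges as
#' "validated" and random decoys as "predicted".
#'
#' @param cfg a [sim_config()].
#' @param mirna_truth `SyntheticTruth` from [simulate_mirna_matrix()].
#' @param allow_empty_regulon permit a truth with no down-regulated miRNAs.
#' @return list with `matrix` (gene [expression_matrix()]), `sites`
#'   (data.frame motif/mirna/gene/n_sites), `interactions` (data.frame
#'   mirna/gene/evidence/source/confidence), and `truth` (regulon and planted
#'   DE genes).
#' @export
simulate_regulated_transcriptome <- function(cfg, mirna_truth,
                                             allow_empty_regulon = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"), inherits(mirna_truth, "SyntheticTruth"))
  de <- mirna_truth$de_features
  regulators <- de[de$effect < 0, , drop = FALSE]
  if (nrow(regulators) == 0 && !allow_empty_regulon) {
    stop("empty regulon: no down-regulated miRNAs in truth ",
         "(set allow_empty_regulon = TRUE to proceed)")
  }
  if (nrow(regulators) * cfg$targets_per_mirna > cfg$n_genes) {
    stop("invalid config: more planted targets than genes")
  }
  with_seed(cfg$seed + 1L, {
    genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
    samples <- .bulk_samples(cfg, prefix = "T")
    n_smp <- nrow(samples)
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    vals <- matrix(baseline, cfg$n_genes, n_smp) +
      matrix(stats::rnorm(cfg$n_genes * n_smp, 0, cfg$noise_sd),
             cfg$n_genes, n_smp)
    dimnames(vals) <- list(genes, samples$sample)
    is_case <- samples$group == "case"

    # disjoint target blocks per regulator
    pool <- sample(genes)
    regulon <- NULL
    if (nrow(regulators) > 0) {
      tg <- pool[seq_len(nrow(regulators) * cfg$targets_per_mirna)]
      regulon <- data.frame(
        mirna = rep(regulators$feature, each = cfg$targets_per_mirna),
        gene = tg,
        suppression = cfg$suppression,
        stringsAsFactors = FALSE
      )
      shift <- cfg$suppression * abs(regulators$effect)
      for (i in seq_len(nrow(regulators))) {
        g <- regulon$gene[regulon$mirna == regulators$feature[i]]
        vals[g, is_case] <- vals[g, is_case] + shift[i]
      }
    } else {
      regulon <- data.frame(mirna = character(0), gene = character(0),
                            suppression = numeric(0))
    }

    # miRNA-independent planted DE genes among the untouched remainder
    rest <- setdiff(genes, regulon$gene)
    n_indep <- min(cfg$n_de_genes, length(rest))
    de_genes <- data.frame(gene = character(0), effect = numeric(0))
    if (n_indep > 0) {
      gi <- sample(rest, n_indep)
      eff <- rep_len(c(1, -1), n_indep) * cfg$effect_size
      vals[gi, is_case] <- vals[gi, is_case] + eff
      de_genes <- data.frame(gene = gi, effect = eff, stringsAsFactors = FALSE)
    }

    # motif decoration: all measured miRNAs get a motif; regulators decorate
    # their targets with 1-3 sites, every motif decorates background genes
    all_mirnas <- unique(c(regulators$feature, de$feature,
                           sprintf("miR-%04d", seq_len(cfg$n_features))))
    motifs <- .make_motifs(all_mirnas)
    site_list <- list()
    if (nrow(regulon) > 0) {
      site_list[[1]] <- data.frame(
        motif = motifs[regulon$mirna],
        mirna = regulon$mirna,
        gene = regulon$gene,
        n_sites = sample(1:3, nrow(regulon), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    n_bg <- max(1L, round(cfg$bg_motif_density * cfg$n_genes))
    bg <- lapply(all_mirnas, function(m) {
      cand <- setdiff(genes, regulon$gene[regulon$mirna == m])
      gsel <- sample(cand, min(n_bg, length(cand)))
      data.frame(motif = motifs[[m]], mirna = m, gene = gsel,
                 n_sites = sample(1:2, length(gsel), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, c(site_list, bg))
    rownames(sites) <- NULL

    inter <- if (nrow(regulon) > 0) {
      data.frame(
        mirna = regulon$mirna, gene = regulon$gene,
        evidence = "validated", source = "synthetic_mirtarbase",
        confidence = "very high", stringsAsFactors = FALSE
      )
    } else {
      data.frame(mirna = character(0), gene = character(0),
                 evidence = character(0), source = character(0),
                 confidence = character(0), stringsAsFactors = FALSE)
    }
    if (cfg$n_decoy_edges > 0) {
      dm <- sample(all_mirnas, cfg$n_decoy_edges, replace = TRUE)
      dg <- sample(genes, cfg$n_decoy_edges, replace = TRUE)
      decoy <- data.frame(
        mirna = dm, gene = dg, evidence = "predicted",
        source = "synthetic_mirdip",
        confidence = sample(c("very high", "high", "medium", "low"),
                            cfg$n_decoy_edges, replace = TRUE),
        stringsAsFactors = FALSE
      )
      keep <- !duplicated(paste(decoy$mirna, decoy$gene, decoy$source)) &
        !paste(decoy$mirna, decoy$gene) %in% paste(inter$mirna, inter$gene)
      inter <- rbind(inter, decoy[keep, , drop = FALSE])
    }
    rownames(inter) <- NULL

    truth <- structure(
      list(regulon = regulon, de_genes = de_genes,
           mirna_de = de, motifs = motifs),
      class = "SyntheticTruth"
    )
    list(matrix = expression_matrix(vals, samples), sites = sites,
         interactions = inter, truth = truth)
  })
}

#' Simulate multi-donor single-cell NB counts with rare planted programs
#'
#' Negative-binomial counts with log-normal gene means, mild log-normal donor
#' scaling, CD8 lineage genes (CD3G/CD8A/CD8B), a 13-gene mitochondrial block,
#' and the Tc17/Treg signature genes. Each cell is assigned a program
#' ("none", "Tc17", "Treg") from its group's frequencies; signature genes of
#' that program are amplified by `signature_fold`.
#'
#' @param cfg a [sim_config()].
#' @return list with `sce` (a `SingleCellExperiment`: sparse counts,
#'   `colData` donor/group/true program, `rowData$mito`) and `truth`
#'   (per-cell labels, requested and realized per-donor frequencies).
#' @export
simulate_single_cell <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  sig_genes <- unique(unlist(cfg$signatures))
  if (is.null(cfg$gene_universe)) {
    special <- c("CD3G", "CD8A", "CD8B", sprintf("MT-SYN%02d", 1:13), sig_genes)
    if (length(special) >= cfg$n_genes_sc) stop("n_genes_sc too small for the gene universe")
    genes <- c(special, sprintf("G%05d", seq_len(cfg$n_genes_sc - length(special))))
  } else {
    genes <- unique(cfg$gene_universe)
  }
  missing_sig <- setdiff(sig_genes, genes)
  if (length(missing_sig)) {
    stop("signature genes absent from gene universe: ",
         paste(missing_sig, collapse = ", "))
  }
  with_seed(cfg$seed + 2L, {
    n_genes <- length(genes)
    mu <- stats::rlnorm(n_genes, meanlog = log(cfg$nb_mean), sdlog = 1.2)
    names(mu) <- genes
    # lineage and mito genes well detected; signature genes moderately
    # expressed so a signature_fold amplification moves them into the top
    # ranks of a cell
    mu["CD3G"] <- 5; mu["CD8A"] <- 3; mu["CD8B"] <- 2
    mu[sprintf("MT-SYN%02d", 1:13)] <- 3
    mu[sig_genes] <- 2

    groups <- names(cfg$program_frequencies)
    donors <- data.frame(
      donor = sprintf("D%02d", seq_len(cfg$n_donors * length(groups))),
      group = rep(groups, each = cfg$n_donors),
      stringsAsFactors = FALSE
    )
    donors$scale <- stats::rlnorm(nrow(donors), 0, 0.1)

    size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
    blocks <- vector("list", nrow(donors))
    meta <- vector("list", nrow(donors))
    for (d in seq_len(nrow(donors))) {
      nc <- cfg$cells_per_donor
      freqs <- cfg$program_frequencies[[donors$group[d]]]
      probs <- c(freqs, none = 1 - sum(freqs))
      labels <- sample(names(probs), nc, replace = TRUE, prob = probs)
      mu_mat <- matrix(mu * donors$scale[d], n_genes, nc)
      for (prog in names(cfg$signatures)) {
        sel <- labels == prog
        if (any(sel)) {
          sg <- match(cfg$signatures[[prog]], genes)
          mu_mat[sg, sel] <- mu_mat[sg, sel] * cfg$signature_fold
        }
      }
      cnt <- matrix(
        stats::rnbinom(n_genes * nc, mu = as.vector(mu_mat), size = size),
        n_genes, nc
      )
      blocks[[d]] <- .as_csparse(cnt)
      meta[[d]] <- data.frame(
        cell = sprintf("%s_C%04d", donors$donor[d], seq_len(nc)),
        donor = donors$donor[d], group = donors$group[d],
        true_program = labels, stringsAsFactors = FALSE
      )
    }
    counts <- do.call(cbind, blocks)
    cells <- do.call(rbind, meta)
    rownames(counts) <- genes
    colnames(counts) <- cells$cell

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(cells, row.names = cells$cell),
      rowData = S4Vectors::DataFrame(
        mito = startsWith(genes, "MT-"), row.names = genes
      )
    )
    realized <- do.call(rbind, lapply(split(cells, cells$donor), function(df) {
      data.frame(
        donor = df$donor[1], group = df$group[1],
        Tc17 = mean(df$true_program == "Tc17"),
        Treg = mean(df$true_program == "Treg"),
        stringsAsFactors = FALSE
      )
    }))
    rownames(realized) <- NULL
    truth <- structure(
      list(cell_labels = stats::setNames(cells$true_program, cells$cell),
           donor_frequencies = realized,
           requested_frequencies = cfg$program_frequencies),
      class = "SyntheticTruth"
    )
    list(sce = sce, truth = truth)
  })
}

#' Simulate a qPCR Ct table with dilution standards and planted fold changes
#'
#' Unknown samples get `Ct = base - log2(fold) * case + noise` per replicate
#' (efficiency 100%, so a planted fold f appears as a -log2(f) case shift);
#' the housekeeping assay "HK" carries no group effect. Standards follow
#' `Ct = intercept + slope * log10(dilution) + noise`.
#'
#' @param cfg a [sim_config()].
#' @param fold_changes named numeric vector of per-assay planted linear folds
#'   (case vs control), all > 0.
#' @return data.frame with columns sample, group, assay, replicate, ct,
#'   dilution (NA for unknowns).
#' @export
simulate_qpcr <- function(cfg, fold_changes) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  if (is.null(names(fold_changes)) || any(names(fold_changes) == "")) {
    stop("`fold_changes` must be a named vector")
  }
  with_seed(cfg$seed + 3L, {
    assays <- c(names(fold_changes), "HK")
    base_ct <- stats::setNames(
      c(stats::runif(length(fold_changes), 22, 28), 20), assays
    )
    folds <- c(fold_changes, HK = 1)
    n <- cfg$qpcr_n_per_group
    samples <- data.frame(
      sample = sprintf("Q%02d", seq_len(2 * n)),
      group = rep(c("control", "case"), each = n),
      stringsAsFactors = FALSE
    )
    grid <- expand.grid(
      sample = samples$sample, assay = assays,
      replicate = seq_len(cfg$qpcr_replicates),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$group <- samples$group[match(grid$sample, samples$sample)]
    grid$ct <- base_ct[grid$assay] -
      log2(folds[grid$assay]) * (grid$group == "case") +
      stats::rnorm(nrow(grid), 0, cfg$qpcr_noise_sd)
    grid$dilution <- NA_real_

    std <- expand.grid(
      dilution = cfg$qpcr_dilutions, assay = assays,
      replicate = seq_len(cfg$qpcr_replicates),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    std$sample <- sprintf("STD_%s_%d", std$assay, match(std$dilution, cfg$qpcr_dilutions))
    std$group <- "standard"
    std$ct <- cfg$qpcr_intercept + cfg$qpcr_slope * log10(std$dilution) +
      stats::rnorm(nrow(std), 0, cfg$qpcr_std_noise_sd)

    cols <- c("sample", "group", "assay", "replicate", "ct", "dilution")
    out <- rbind(grid[, cols], std[, cols])
    rownames(out) <- NULL
    out
  })
}
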