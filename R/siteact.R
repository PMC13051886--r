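#' Binding-site enrichment among DEGs with activity-direction inference
#'
#' For every 7-mer motif and each DE direction a 2x2 table is built at the
#' gene level: `a` = DEGs of that direction bearing the motif, `b` = other
#' universe genes bearing it, `c` = DEGs lacking it, `d` = the rest. The
#' two-sided Fisher exact p (minimum-likelihood convention, as in
#' `fisher.test`) is combined with the sample odds ratio (Haldane-Anscombe
#' +0.5 when any cell is zero), reported on the log2 scale. A motif enriched
#' among up-regulated genes implies reduced activity of its miRNAs
#' ("Downregulated"); enrichment among down-regulated genes implies
#' "Upregulated". BH adjustment runs across all motif x direction tests;
#' by default only enriched rows (`OR > 1`) passing `adj_p_max` are returned.
#' `site_overlap` (total sites in the overlapping DEGs) is descriptive only.
#'
#' @param sites data.frame with columns motif, mirna, gene, n_sites.
#' @param de_up,de_down disjoint character vectors of DEGs by direction,
#'   subsets of `universe`.
#' @param universe character vector of all genes tested for DE.
#' @param adj_p_max BH-adjusted significance cutoff (default 0.05).
#' @param keep_all return every motif x direction test (activity NA when
#'   OR <= 1) instead of filtering.
#' @return data.frame: motif, mirnas (comma-joined), estimated_activity,
#'   size, overlap, site_overlap, log2_or, p, adj_p, direction.
#' @export
site_enrichment <- function(sites, de_up, de_down, universe,
                            adj_p_max = 0.05, keep_all = FALSE) {
  if (length(universe) == 0) stop("empty gene universe")
  if (length(intersect(de_up, de_down))) stop("de_up and de_down overlap")
  if (!all(c(de_up, de_down) %in% universe)) stop("DEGs must be in the universe")
  if (any(nchar(sites$motif) != 7)) stop("motifs must be 7-mers")
  universe <- unique(universe)
  N <- length(universe)

  sites <- sites[sites$gene %in% universe, , drop = FALSE]
  motif_genes <- lapply(split(sites$gene, sites$motif), unique)
  motif_mirnas <- lapply(split(sites$mirna, sites$motif), unique)
  # site counts per unique (motif, gene): families share sites, count once
  key <- !duplicated(paste(sites$motif, sites$gene))
  per_gene_sites <- split(
    stats::setNames(sites$n_sites[key], sites$gene[key]), sites$motif[key]
  )

  de_lists <- list(up = unique(de_up), down = unique(de_down))
  rows <- list()
  for (motif in names(motif_genes)) {
    carriers <- motif_genes[[motif]]
    size <- length(carriers)
    for (dir in c("up", "down")) {
      deg <- de_lists[[dir]]
      a <- length(intersect(deg, carriers))
      b <- size - a
      cc <- length(deg) - a
      dd <- N - size - cc
      tab <- matrix(c(a, b, cc, dd), 2)
      p <- min(1, stats::fisher.test(tab)$p.value)  # guard FP overshoot
      if (any(tab == 0)) {
        or <- ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
      } else {
        or <- (a * dd) / (b * cc)
      }
      site_ov <- sum(per_gene_sites[[motif]][
        names(per_gene_sites[[motif]]) %in% deg])
      rows[[paste(motif, dir)]] <- data.frame(
        motif = motif,
        mirnas = paste(sort(motif_mirnas[[motif]]), collapse = ","),
        estimated_activity = if (or > 1) {
          if (dir == "up") "Downregulated" else "Upregulated"
        } else NA_character_,
        size = size, overlap = a, site_overlap = site_ov,
        log2_or = log2(or), p = p, direction = dir,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adj_p <- bh_adjust(out$p)
  if (!keep_all) {
    out <- out[!is.na(out$estimated_activity) & out$adj_p < adj_p_max, ,
               drop = FALSE]
  }
  out <- out[order(out$p, out$motif), c(
    "motif", "mirnas", "estimated_activity", "size", "overlap",
    "site_overlap", "log2_or", "p", "adj_p", "direction"
  )]
  rownames(out) <- NULL
  out
}

#' Intersect significant motif activities with observed DE-miRNAs
#'
#' A motif row is influential when at least one of its miRNAs is itself
#' differentially expressed in the direction matching the estimated activity
#' (a down-regulated miRNA whose motif is enriched among up-regulated genes,
#' and vice versa). The miRNA list of each kept row is pruned to the
#' concordant members.
#'
#' @param rows output of [site_enrichment()].
#' @param de_mirnas data.frame with columns `mirna` and `direction`
#'   ("up"/"down" or "Upregulated"/"Downregulated").
#' @return the concordant subset of `rows` with pruned `mirnas`.
#' @export
intersect_influential <- function(rows, de_mirnas) {
  if (!all(c("mirna", "direction") %in% names(de_mirnas))) {
    stop("de_mirnas needs columns 'mirna' and 'direction'")
  }
  dir_map <- c(up = "Upregulated", down = "Downregulated",
               Upregulated = "Upregulated", Downregulated = "Downregulated")
  dir <- dir_map[as.character(de_mirnas$direction)]
  if (anyNA(dir)) stop("directions must be up/down or Upregulated/Downregulated")
  de_dir <- stats::setNames(dir, de_mirnas$mirna)

  keep <- logical(nrow(rows))
  pruned <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    mir <- strsplit(rows$mirnas[i], ",", fixed = TRUE)[[1]]
    conc <- mir[!is.na(de_dir[mir]) & de_dir[mir] == rows$estimated_activity[i]]
    keep[i] <- length(conc) > 0
    pruned[i] <- paste(conc, collapse = ",")
  }
  out <- rows[keep, , drop = FALSE]
  out$mirnas <- pruned[keep]
  rownames(out) <- NULL
  out
}

#' Assemble the miRNA-target regulatory network
#'
#' Edges are the supplied interactions whose miRNA is influential (per
#' [intersect_influential()]) and whose gene is differentially expressed in
#' the direction opposite the miRNA's estimated activity (down-miRNA -> up
#' gene, up-miRNA -> down gene). Predicted interactions are kept only at the
#' configured confidence classes. Target genes are annotated by
#' overrepresentation against the supplied pathway sets, with the universe
#' being every gene carrying at least one (confidence-filtered) interaction.
#'
#' @param influential output of [intersect_influential()].
#' @param interactions data.frame mirna/gene/evidence/source (optional
#'   confidence column).
#' @param de_genes a `DEResult` for the gene layer.
#' @param pathways named list of gene sets (may be NULL to skip ORA).
#' @param q_max,min_abs_fc DEG thresholds passed to [call_de()].
#' @param confidence_keep confidence classes accepted for predicted edges.
#' @param ora_adj_p_max BH cutoff for the pathway annotation (default 0.1).
#' @param min_set_size minimum pathway size for the ORA.
#' @return list with `edges` (data.frame), `graph` (bipartite igraph),
#'   `gene_ora` (full ORA table), `pathways_enriched`, and `universe`.
#' @export
build_network <- function(influential, interactions, de_genes, pathways = NULL,
                          q_max = 0.1, min_abs_fc = 1.5,
                          confidence_keep = c("very high", "high"),
                          ora_adj_p_max = 0.1, min_set_size = 8) {
  if (nrow(interactions) == 0) stop("empty interaction table")
  if (!is.null(interactions$confidence)) {
    keep <- interactions$evidence == "validated" |
      interactions$confidence %in% confidence_keep
    interactions <- interactions[keep, , drop = FALSE]
  }
  deg <- call_de(de_genes, q_max = q_max, min_abs_fc = min_abs_fc)

  act <- list()
  for (i in seq_len(nrow(influential))) {
    for (m in strsplit(influential$mirnas[i], ",", fixed = TRUE)[[1]]) {
      act[[m]] <- influential$estimated_activity[i]
    }
  }
  mir_act <- unlist(act)

  gene_dir <- c(
    stats::setNames(rep("up", length(deg$up)), deg$up),
    stats::setNames(rep("down", length(deg$down)), deg$down)
  )
  sel <- interactions$mirna %in% names(mir_act) &
    !is.na(gene_dir[interactions$gene]) &
    ((mir_act[interactions$mirna] == "Downregulated" &
        gene_dir[interactions$gene] == "up") |
       (mir_act[interactions$mirna] == "Upregulated" &
          gene_dir[interactions$gene] == "down"))
  edges <- interactions[which(sel), , drop = FALSE]
  if (nrow(edges) == 0) warning("regulatory network is empty")
  edges$mirna_activity <- unname(mir_act[edges$mirna])
  edges$gene_direction <- unname(gene_dir[edges$gene])
  rownames(edges) <- NULL

  universe <- unique(interactions$gene)
  gene_ora <- NULL
  enriched <- NULL
  if (!is.null(pathways) && nrow(edges) > 0) {
    targets <- intersect(unique(edges$gene), universe)
    gene_ora <- ora_hypergeometric(targets, universe, pathways,
                                   min_size = min_set_size)
    enriched <- gene_ora[gene_ora$adj_p < ora_adj_p_max, , drop = FALSE]
  }

  g <- igraph::make_empty_graph(directed = TRUE)
  if (nrow(edges) > 0) {
    verts <- data.frame(
      name = c(unique(edges$mirna), unique(edges$gene)),
      type = c(rep("mirna", length(unique(edges$mirna))),
               rep("gene", length(unique(edges$gene)))),
      stringsAsFactors = FALSE
    )
    verts$de_direction <- ifelse(
      verts$type == "mirna",
      ifelse(mir_act[verts$name] == "Downregulated", "down", "up"),
      gene_dir[verts$name]
    )
    g <- igraph::graph_from_data_frame(
      edges[, c("mirna", "gene", "evidence", "source")],
      directed = TRUE, vertices = verts
    )
  }
  list(edges = edges, graph = g, gene_ora = gene_ora,
       pathways_enriched = enriched, universe = universe)
}

#' Export a regulatory network
#'
#' Writes the edge list as TSV and, optionally, the graph as GraphML.
#'
#' @param net output of [build_network()].
#' @param edge_path TSV path for the edge list.
#' @param graphml_path optional GraphML path.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  write_tsv_table(net$edges, edge_path)
  if (!is.null(graphml_path) && igraph::vcount(net$graph) > 0) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
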