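# End-to-end orchestration: ortholog pairing -> differential expression ->
# promoter motif analysis -> hub-centered networks, with persisted stage
# tables and a machine-readable summary.

#' Pipeline configuration
#'
#' @param synth a [synth_config()]; used when `input_dir` is `NULL`.
#' @param input_dir optional directory with `counts_A.tsv`, `counts_B.tsv`,
#'   `hits.tsv` (alignment hit table) and `promoters_A.fasta`; when given,
#'   the pipeline runs on these files instead of synthetic data.
#' @param lfc_threshold,p_threshold DE classification thresholds
#'   (|log2FC| > 2, raw p < 0.01 by default).
#' @param K number of temporal clusters (0 disables clustering).
#' @param r_min,r_core co-expression thresholds for the network and the core
#'   regulon.
#' @param network_motif motif whose promoter density selects network genes.
#' @param density_window TSS-relative window for motif density counting.
#' @param hub_id hub gene for the genotype-A network; `NULL` uses the planted
#'   hub (synthetic mode) or the selected gene with the highest co-expression
#'   degree.
#' @param motif_defs motif definition table.
#' @param seed pipeline seed (also forwarded to the generator when `synth`
#'   carries no explicit seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            input_dir = NULL,
                            lfc_threshold = 2, p_threshold = 0.01,
                            K = 8, r_min = 0.8, r_core = 0.9,
                            network_motif = "BRRE",
                            density_window = c(-1200, 500),
                            hub_id = NULL,
                            motif_defs = default_motifs(),
                            seed = 7) {
  cfg <- list(synth = synth, input_dir = input_dir,
              lfc_threshold = lfc_threshold, p_threshold = p_threshold,
              K = as.integer(K), r_min = r_min, r_core = r_core,
              network_motif = network_motif,
              density_window = as.integer(density_window),
              hub_id = hub_id, motif_defs = motif_defs,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read promoter regions from a FASTA written by [write_promoters_fasta()]
#' @param path FASTA file.
#' @return promoter data.frame.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  gene <- sub("\\s.*$", "", hdr)
  strand <- sub(".*strand=(\\S+).*", "\\1", hdr)
  win <- regmatches(hdr, regexpr("window=\\[-?[0-9]+,-?[0-9]+\\)", hdr))
  ws <- as.integer(sub("window=\\[(-?[0-9]+),.*", "\\1", win))
  we <- as.integer(sub(".*,(-?[0-9]+)\\)", "\\1", win))
  data.frame(gene_id = gene, strand = strand, tss_genomic = NA_integer_,
             win_start = ws, win_end = we,
             truncated = grepl("truncated", hdr),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Run the full comparative pipeline
#'
#' Executes ortholog pairing, normalization and per-timepoint DE testing for
#' both genotypes, response classification, cross-species concordance,
#' promoter motif scanning with density classes, gene selection, hub-centered
#' network assembly and fragmentation for both genotypes, and (optionally)
#' temporal clustering. All stage tables are written to `out_dir` together
#' with GraphML networks, a log, and `summary.json` holding exactly these
#' keys: `config_hash`, `seed`, `n_genes`, `de_class_counts`, `concordance`,
#' `density_class_counts`, `n_network_genes`, `core_regulon_size`,
#' `fragmentation`, `cluster_sizes`. Identical config and seed give an
#' identical summary.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(format(length(log_lines) + 1), ": ", ...)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # config hash over the serialized configuration
  cfg_json <- jsonlite::serializeJSON(unclass(config))
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(as.character(cfg_json), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  note("coldregulon ", as.character(utils::packageVersion("coldregulon")),
       " seed=", config$seed, " config=", cfg_hash)

  # ---- inputs ----
  truth <- NULL
  if (is.null(config$input_dir)) {
    ds <- stage("simulate", generate_dataset(config$synth))
    counts_a <- ds$counts_a; counts_b <- ds$counts_b
    promoters <- ds$promoters
    orthologs <- ds$orthologs[!duplicated(ds$orthologs$gene_b), ]
    truth <- ds$truth
    note("simulated dataset: ", nrow(counts_a$counts), " A genes, ",
         nrow(counts_b$counts), " B genes")
  } else {
    counts_a <- stage("load", read_counts_tsv(
      file.path(config$input_dir, "counts_A.tsv")))
    counts_b <- stage("load", read_counts_tsv(
      file.path(config$input_dir, "counts_B.tsv")))
    promoters <- stage("load", read_promoters_fasta(
      file.path(config$input_dir, "promoters_A.fasta")))
    hits_tab <- stage("orthologs", read_hits_tsv(
      file.path(config$input_dir, "hits.tsv")))
    om <- stage("orthologs", build_ortholog_map(hits_tab))
    orthologs <- data.frame(gene_a = om$locus_a, gene_b = om$locus_b,
                            stringsAsFactors = FALSE)
  }
  write_pairs_tsv(orthologs, file.path(out_dir, "ortholog_pairs.tsv"))

  # ---- expression ----
  de <- list(); cls <- list()
  for (gt in c("A", "B")) {
    cm <- if (gt == "A") counts_a else counts_b
    nrm <- stage("normalize", normalize_counts(cm))
    disp <- stage("dispersion", estimate_dispersion(cm, nrm$size_factors))
    tab <- stage("de", de_table(cm, gt, disp, nrm$size_factors))
    cl <- classify_response(tab, config$lfc_threshold, config$p_threshold)
    tab$class <- cl[tab$gene_id]
    utils::write.table(tab, file.path(out_dir, paste0("de_", gt, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de[[gt]] <- tab; cls[[gt]] <- cl
    if (gt == "A") { nrm_a <- nrm; disp_a <- disp }
    note("DE genotype ", gt, ": ",
         paste(names(table(cl)), table(cl), collapse = " ", sep = "="))
  }
  conc <- stage("concordance",
                ortholog_concordance(cls$A, cls$B, orthologs))

  # ---- promoter motifs ----
  defs <- config$motif_defs[!is.na(config$motif_defs$iupac), , drop = FALSE]
  hits <- stage("scan", scan_motifs(promoters, defs))
  utils::write.table(hits, file.path(out_dir, "motif_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dens <- stage("density", density_classes(hits, promoters$gene_id,
                                           config$network_motif,
                                           config$density_window))
  utils::write.table(dens, file.path(out_dir, "motif_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  up_a <- names(cls$A)[cls$A == "up"]
  enr <- if (length(up_a))
    stage("enrichment", positional_enrichment(
      hits, intersect(up_a, promoters$gene_id), promoters$gene_id))
  else NULL
  if (!is.null(enr))
    utils::write.table(enr, file.path(out_dir, "motif_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- networks ----
  sel <- stage("select", select_network_genes(dens, cls$A))
  prof_a <- fc_profiles(de$A)
  prof_b <- fc_profiles(de$B)
  hub_a <- config$hub_id
  if (is.null(hub_a) && !is.null(truth)) hub_a <- truth$hub_id
  frag <- list(); core_size <- list(); cluster_sizes <- NULL
  if (length(sel) >= 2) {
    # the designated hub anchors the regulon: keep it in the node set even
    # if it narrowly misses the DE/density filter
    nodes_a <- if (!is.null(hub_a) && hub_a %in% rownames(prof_a))
      union(sel, hub_a) else sel
    edges_a <- stage("network",
                     coexpression_edges(prof_a, nodes_a, config$r_min))
    if (is.null(hub_a) || !hub_a %in% nodes_a) {
      deg <- table(c(edges_a$gene_u, edges_a$gene_v))
      hub_a <- names(deg)[which.max(deg)]
      note("hub defaulted to highest-degree selected gene ", hub_a)
    }
    net_a <- stage("network", assemble_regulon(edges_a, nodes_a, hub_a))
    core_a <- core_regulon(net_a, config$r_core)
    frag$A <- fragmentation(edges_a, nodes_a, hub_a)
    core_size$A <- length(core_a)
    export_graph(net_a, file.path(out_dir, "network_A.graphml"),
                 file.path(out_dir, "network_A_edges.tsv"),
                 node_attrs = data.frame(gene_id = nodes_a,
                                         response = unname(cls$A[nodes_a])))
    # genotype-B network over the orthologs of the selected genes
    map_b <- orthologs$gene_b[match(nodes_a, orthologs$gene_a)]
    nodes_b <- unique(map_b[!is.na(map_b) & map_b %in% rownames(prof_b)])
    hub_b <- orthologs$gene_b[match(hub_a, orthologs$gene_a)]
    if (length(nodes_b) >= 2 && !is.na(hub_b) && hub_b %in% nodes_b) {
      edges_b <- coexpression_edges(prof_b, nodes_b, config$r_min)
      net_b <- assemble_regulon(edges_b, nodes_b, hub_b)
      core_size$B <- length(core_regulon(net_b, config$r_core))
      frag$B <- fragmentation(edges_b, nodes_b, hub_b)
      export_graph(net_b, file.path(out_dir, "network_B.graphml"),
                   file.path(out_dir, "network_B_edges.tsv"))
    } else note("genotype-B network skipped: too few mapped nodes")
    note("network: ", length(sel), " genes selected (", length(nodes_a),
         " nodes with hub), hub ", hub_a)
  } else note("network skipped: fewer than 2 selected genes")

  # ---- clustering ----
  if (config$K >= 2) {
    de_genes <- names(cls$A)[cls$A != "unchanged"]
    if (length(de_genes) >= config$K) {
      ca <- stage("cluster", nb_kmeans(
        nrm_a$normalized[de_genes, , drop = FALSE],
        counts_a$samples$timepoint_hr, K = config$K,
        dispersion = disp_a[de_genes], seed = config$seed))
      utils::write.table(
        data.frame(gene_id = names(ca$cluster), cluster = ca$cluster),
        file.path(out_dir, "clusters_A.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      cluster_sizes <- as.integer(table(factor(ca$cluster,
                                               seq_len(config$K))))
    } else note("clustering skipped: fewer DE genes than clusters")
  }

  summary <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    n_genes = list(A = nrow(counts_a$counts), B = nrow(counts_b$counts)),
    de_class_counts = lapply(cls, function(cl)
      as.list(table(factor(cl, c("up", "down", "unchanged"))))),
    concordance = c(as.list(conc$percent),
                    list(n_pairs = conc$n_pairs,
                         n_excluded = conc$n_excluded)),
    density_class_counts = as.list(table(factor(
      dens$class, c("low", "high", "very_high")))),
    n_network_genes = length(sel),
    core_regulon_size = core_size,
    fragmentation = frag,
    cluster_sizes = cluster_sizes)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, logf)
  invisible(summary)
}
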