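# Hub-centered co-expression regulon assembly and fragmentation metrics.
#
# Networks are built over BRRE-dense cold-upregulated genes from Pearson
# correlations of 4-point log2 fold-change profiles; tiers are BFS depth from
# the hub (primary/secondary/tertiary, deeper collapsed to tertiary) and
# fragmentation is quantified by connected components and the fraction of
# nodes still coupled to the hub.

#' Fold-change profiles from a DE table
#'
#' @param de DE table from [de_table()].
#' @return matrix, genes x stress timepoints, of log2 fold changes (rows
#'   ordered as in the table; timepoint order fixed by the table's
#'   `timepoints_hr` attribute). Genes with any missing value are dropped
#'   with a message.
#' @export
fc_profiles <- function(de) {
  lfc_cols <- grep("^log2fc_", names(de), value = TRUE)
  lfc_cols <- lfc_cols[order(as.integer(sub("^log2fc_", "", lfc_cols)))]
  m <- as.matrix(de[lfc_cols])
  rownames(m) <- de$gene_id
  bad <- rowSums(!is.finite(m)) > 0
  if (any(bad)) {
    message("fc_profiles: dropping ", sum(bad), " gene(s) with missing values")
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Pairwise co-expression edges
#'
#' Pearson correlation between profile vectors for all pairs within a gene
#' set; an edge is kept iff `r >= r_min`. Constant profiles (undefined
#' correlation) contribute no edges and are reported with a message.
#'
#' @param profiles genes x timepoints matrix (e.g. [fc_profiles()]).
#' @param genes gene set to consider (default all rows).
#' @param r_min correlation threshold in (0,1).
#' @return data.frame `gene_u`, `gene_v`, `weight`, one row per undirected
#'   edge with `gene_u < gene_v`.
#' @export
coexpression_edges <- function(profiles, genes = rownames(profiles),
                               r_min = 0.8) {
  if (r_min <= 0 || r_min >= 1) stop("r_min must be in (0,1)")
  if (ncol(profiles) < 3) stop("need >= 3 profile dimensions")
  genes <- intersect(genes, rownames(profiles))
  empty <- data.frame(gene_u = character(0), gene_v = character(0),
                      weight = numeric(0))
  if (length(genes) < 2) return(empty)
  m <- profiles[genes, , drop = FALSE]
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    message("coexpression_edges: excluding ", sum(const),
            " constant profile(s)")
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2) return(empty)
  cc <- stats::cor(t(m))
  idx <- which(upper.tri(cc) & cc >= r_min, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  res <- data.frame(gene_u = rownames(cc)[idx[, 1]],
                    gene_v = rownames(cc)[idx[, 2]],
                    weight = cc[idx], stringsAsFactors = FALSE)
  swap <- res$gene_u > res$gene_v
  tmp <- res$gene_u[swap]; res$gene_u[swap] <- res$gene_v[swap]
  res$gene_v[swap] <- tmp
  res <- res[order(res$gene_u, res$gene_v), ]
  rownames(res) <- NULL
  res
}

#' Select network genes: BRRE-dense and cold-upregulated
#'
#' @param density data.frame from [density_classes()].
#' @param classes named response-class vector from [classify_response()].
#' @return character vector of genes with density class `high` or
#'   `very_high` and response class `up` (empty result warns).
#' @export
select_network_genes <- function(density, classes) {
  dense <- density$gene_id[density$class %in% c("high", "very_high")]
  up <- names(classes)[classes == "up"]
  sel <- intersect(dense, up)
  if (!length(sel)) warning("no gene passes the density + upregulation filter")
  sel
}

#' @noRd
as_igraph <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[c("gene_u", "gene_v", "weight")]
    else data.frame(gene_u = character(0), gene_v = character(0),
                    weight = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g
}

#' Assemble a hub-centered regulon network
#'
#' BFS depth from the hub over the retained edges assigns tiers: 1 = primary,
#' 2 = secondary, >= 3 = tertiary; nodes unreachable from the hub are labeled
#' `unlinked` but retained (they form the fragmented remainder).
#'
#' @param edges edge data.frame from [coexpression_edges()].
#' @param nodes node set (must contain `hub_id`).
#' @param hub_id hub gene id.
#' @return object of class `regulon_network`: list with `nodes`, `edges`,
#'   `hub_id`, `tier` (named: `hub`, `primary`, `secondary`, `tertiary`,
#'   `unlinked`).
#' @export
assemble_regulon <- function(edges, nodes, hub_id) {
  if (!hub_id %in% nodes) stop("hub ", hub_id, " not in node set")
  edges <- edges[edges$gene_u %in% nodes & edges$gene_v %in% nodes, ,
                 drop = FALSE]
  g <- as_igraph(edges, nodes)
  d <- igraph::distances(g, v = hub_id, weights = NA)[1, ]
  tier <- ifelse(!is.finite(d), "unlinked",
                 ifelse(d == 0, "hub",
                        ifelse(d == 1, "primary",
                               ifelse(d == 2, "secondary", "tertiary"))))
  names(tier) <- names(d)
  tier <- tier[nodes]
  structure(list(nodes = nodes, edges = edges, hub_id = hub_id, tier = tier),
            class = "regulon_network")
}

#' @export
print.regulon_network <- function(x, ...) {
  cat("regulon_network: hub", x$hub_id, "|", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  print(table(tier = factor(x$tier, c("hub", "primary", "secondary",
                                      "tertiary", "unlinked"))))
  invisible(x)
}

#' Core regulon: the hub plus its tightly co-expressed direct neighbors
#'
#' @param network a `regulon_network`.
#' @param r_core minimum edge weight to the hub (should be `>= r_min` used
#'   for the network).
#' @return character vector: the hub and its direct neighbors with edge
#'   weight `>= r_core`.
#' @export
core_regulon <- function(network, r_core = 0.9) {
  e <- network$edges
  inc <- e[(e$gene_u == network$hub_id | e$gene_v == network$hub_id) &
             e$weight >= r_core, , drop = FALSE]
  nb <- setdiff(unique(c(inc$gene_u, inc$gene_v)), network$hub_id)
  c(network$hub_id, nb)
}

#' Network fragmentation report
#'
#' Connected components of the graph induced on the node set, the fraction of
#' nodes in the largest component, the hub's degree, the fraction of nodes
#' reachable from the hub, and an `intact` flag (single component).
#'
#' @param edges edge data.frame.
#' @param nodes node set.
#' @param hub_id hub gene id (must be in `nodes`).
#' @return list with `n_components`, `largest_component_fraction`,
#'   `hub_degree`, `hub_coupled_fraction`, `intact`.
#' @export
fragmentation <- function(edges, nodes, hub_id) {
  if (!length(nodes)) stop("node set must be non-empty")
  if (!hub_id %in% nodes) stop("hub ", hub_id, " not in node set")
  edges <- edges[edges$gene_u %in% nodes & edges$gene_v %in% nodes, ,
                 drop = FALSE]
  g <- as_igraph(edges, nodes)
  comp <- igraph::components(g)
  hub_comp <- comp$membership[hub_id]
  list(n_components = comp$no,
       largest_component_fraction = max(comp$csize) / length(nodes),
       hub_degree = unname(igraph::degree(g, hub_id)),
       hub_coupled_fraction = unname(sum(comp$membership == hub_comp) /
                                       length(nodes)),
       intact = comp$no == 1L)
}

#' Export a regulon network to GraphML and an edge-list TSV
#'
#' Node attributes: tier plus any columns of `node_attrs`; edge attributes:
#' `weight` and `length = 1 - weight` for layout tools.
#'
#' @param network a `regulon_network`.
#' @param graphml_path output GraphML file.
#' @param edgelist_path optional output TSV of edges.
#' @param node_attrs optional data.frame keyed by `gene_id` with extra node
#'   attributes (e.g. density class, response class).
#' @return invisibly, the paths written.
#' @export
export_graph <- function(network, graphml_path, edgelist_path = NULL,
                         node_attrs = NULL) {
  g <- as_igraph(network$edges, network$nodes)
  igraph::V(g)$tier <- unname(network$tier[igraph::V(g)$name])
  if (!is.null(node_attrs)) {
    stopifnot("gene_id" %in% names(node_attrs))
    i <- match(igraph::V(g)$name, node_attrs$gene_id)
    for (col in setdiff(names(node_attrs), "gene_id")) {
      v <- node_attrs[[col]][i]
      if (is.factor(v)) v <- as.character(v)
      g <- igraph::set_vertex_attr(g, col, value = v)
    }
  }
  if (igraph::ecount(g) > 0)
    igraph::E(g)$length <- 1 - igraph::E(g)$weight
  tryCatch(igraph::write_graph(g, graphml_path, format = "graphml"),
           error = function(e) stop("GraphML export to ", graphml_path,
                                    " failed: ", conditionMessage(e)))
  if (!is.null(edgelist_path))
    utils::write.table(network$edges, edgelist_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(graphml = graphml_path, edgelist = edgelist_path))
}

#' Read back a GraphML regulon export
#' @param path GraphML file written by [export_graph()].
#' @return list with `nodes`, `edges` (gene_u, gene_v, weight), `tier`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- if (nrow(el)) data.frame(gene_u = pmin(el$from, el$to),
                                    gene_v = pmax(el$from, el$to),
                                    weight = el$weight,
                                    stringsAsFactors = FALSE)
  else data.frame(gene_u = character(0), gene_v = character(0),
                  weight = numeric(0))
  edges <- edges[order(edges$gene_u, edges$gene_v), , drop = FALSE]
  rownames(edges) <- NULL
  tier <- if ("tier" %in% igraph::vertex_attr_names(g))
    stats::setNames(igraph::V(g)$tier, igraph::V(g)$name) else NULL
  list(nodes = igraph::V(g)$name, edges = edges, tier = tier)
}
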