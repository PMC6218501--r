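# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths (no shared regex machinery, no igraph).

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# all start positions (1-based) where the IUPAC motif matches, checked
# position by position with character-set membership
oracle_match_starts <- function(seq, iupac) {
  sc <- strsplit(toupper(seq), "")[[1]]
  mc <- strsplit(toupper(iupac), "")[[1]]
  w <- length(mc); L <- length(sc)
  if (L < w) return(integer(0))
  ok <- rep(TRUE, L - w + 1)
  for (j in seq_len(w)) {
    allowed <- ORACLE_IUPAC[[mc[j]]]
    ok <- ok & sc[j:(L - w + j)] %in% allowed
  }
  which(ok)
}

# both-strand scan with the palindrome rule (identical span on both strands
# reported once, on +); returns data.frame(position [1-based], strand)
oracle_scan <- function(seq, iupac) {
  fwd <- oracle_match_starts(seq, iupac)
  rev <- setdiff(oracle_match_starts(seq, oracle_revcomp(iupac)), fwd)
  data.frame(position = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))),
             stringsAsFactors = FALSE)
}

# exact hypergeometric upper tail P(X >= k) by direct summation
oracle_hyper_tail <- function(k, K, N, n) {
  i <- max(k, max(0, n - (N - K))):min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# connected components by union-find
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    ru <- find(edges$gene_u[i]); rv <- find(edges$gene_v[i])
    if (ru != rv) parent[[ru]] <- rv
  }
  vapply(nodes, find, character(1))
}

# BFS hop depth from a source over an undirected edge list (Inf = unreachable)
oracle_bfs_depth <- function(nodes, edges, source) {
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[source] <- 0
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(edges$gene_v[edges$gene_u == v], edges$gene_u[edges$gene_v == v])
      new <- nb[is.infinite(d[nb])]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# independently coded median-of-ratios size factors (own median logic,
# geometric-mean-1 scale)
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[keep, , drop = FALSE]
  ref <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  mid <- function(x) {
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  sf <- apply(sub, 2, function(col) mid(col / ref))
  sf / prod(sf)^(1 / length(sf))
}

# random ACGT string
rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# random alignment hit table
rand_hits <- function(n_query, n_target, n_hits) {
  data.frame(
    query_id = sample(sprintf("Q%03d", seq_len(n_query)), n_hits, TRUE),
    target_id = sample(sprintf("T%03d", seq_len(n_target)), n_hits, TRUE),
    aln_length = sample(50:500, n_hits, TRUE),
    identity = round(stats::runif(n_hits, 0.7, 1), 3),
    query_coverage = round(stats::runif(n_hits, 0.3, 1), 3),
    stringsAsFactors = FALSE)
}

# random undirected weighted edge list over the given nodes
rand_edges <- function(nodes, p = 0.15) {
  cmb <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(cmb)) < p
  data.frame(gene_u = cmb[keep, 1], gene_v = cmb[keep, 2],
             weight = round(stats::runif(sum(keep), 0.8, 1), 3),
             stringsAsFactors = FALSE)
}

# quick count_matrix from a counts matrix with t0/t24-style column groups
make_cm <- function(counts, timepoints, genotype = "A") {
  nrep <- ncol(counts) / length(timepoints)
  samples <- data.frame(
    sample = paste(genotype, paste0("t", rep(timepoints, each = nrep)),
                   paste0("r", rep(seq_len(nrep), length(timepoints))),
                   sep = "_"),
    genotype = genotype,
    timepoint_hr = rep(timepoints, each = nrep),
    replicate = rep(seq_len(nrep), length(timepoints)),
    stringsAsFactors = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  count_matrix(counts, samples)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
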