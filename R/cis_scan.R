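# Promoter extraction and cis-element analysis: strand-aware TSS-relative
# windows, IUPAC motif scanning on both strands, positional enrichment among
# upregulated genes, motif-density classes and spatial map tables.

#' Default cis-element motif definitions
#'
#' IUPAC strings for the shipped motifs, drawn from standard PLACE/literature
#' usage. Motifs without an established consensus (`GS2`, `JRRE`) ship with
#' `NA` and must be supplied by the user before use; they error at use rather
#' than being silently guessed.
#'
#' @return data.frame with columns `name`, `iupac`, `class_tag`.
#' @export
default_motifs <- function() {
  data.frame(
    name = c("BRRE", "E-box", "ABRE-like", "ABRE", "DRE/CRT", "as1/ocs",
             "Myb2", "hex-3", "GARE", "GS2", "JRRE"),
    iupac = c("CGTGYG", "CANNTG", "ACGTGKC", "ACGTGGC", "RCCGAC", "TGACG",
              "YAACKG", "ACGTCA", "TAACARA", NA, NA),
    class_tag = c("BL", "E-box", "ABA", "ABA", "DREB", "ROS",
                  "ROS", "ABA", "GA", "ZT", "JA"),
    stringsAsFactors = FALSE)
}

#' Resolve a motif name to its IUPAC string
#' @param name motif name.
#' @param motifs motif definition table (see [default_motifs()]).
#' @return IUPAC string.
#' @export
motif_iupac <- function(name, motifs = default_motifs()) {
  i <- match(name, motifs$name)
  if (is.na(i)) stop("unknown motif: ", name)
  iu <- motifs$iupac[i]
  if (is.na(iu)) stop("motif ", name, " has no configured IUPAC string; ",
                      "supply one in the motif table")
  ch <- strsplit(toupper(iu), "", fixed = TRUE)[[1]]
  if (!all(ch %in% names(IUPAC_MAP))) stop("invalid IUPAC in motif ", name)
  iu
}

#' Extract TSS-relative promoter windows from a genome and gene models
#'
#' For + strand genes the genomic slice is `[tss + start, tss + end)`
#' (0-based, TSS at the gene's 5' end); for - strand genes the mirrored slice
#' is reverse-complemented so that TSS-relative coordinates are strand-aware
#' (position -10 is 10 bases upstream on the gene's strand). Windows
#' truncated at contig edges are flagged; genes on missing contigs are
#' skipped with a warning.
#'
#' @param genome named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param models data.frame with columns `gene_id`, `seqid`, `start`, `end`
#'   (1-based inclusive), `strand`, or a GFF3 path (gene features are used).
#' @param window TSS-relative half-open interval, default `c(-3000, 2000)`.
#' @return data.frame with columns `gene_id`, `strand`, `tss_genomic`
#'   (0-based), `win_start`, `win_end` (possibly tightened at contig edges),
#'   `truncated`, `sequence`.
#' @export
extract_promoters <- function(genome, models, window = c(-3000, 2000)) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- stats::setNames(as.character(genome), nm)
  }
  if (is.character(models) && length(models) == 1 && file.exists(models))
    models <- read_gene_models_gff3(models)
  stopifnot(all(c("gene_id", "seqid", "start", "end", "strand") %in%
                  names(models)))
  out <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    if (!g$seqid %in% names(genome)) {
      warning("gene ", g$gene_id, " on missing contig ", g$seqid, "; skipped")
      next
    }
    contig <- genome[[g$seqid]]
    if (is.null(contig) || is.na(contig)) {
      warning("gene ", g$gene_id, " on missing contig ", g$seqid, "; skipped")
      next
    }
    L <- nchar(contig)
    tss0 <- if (g$strand == "+") g$start - 1L else g$end - 1L  # 0-based
    if (g$strand == "+") {
      lo <- tss0 + window[1]; hi <- tss0 + window[2]           # [lo, hi)
      clo <- max(lo, 0L); chi <- min(hi, L)
      seq <- substr(contig, clo + 1L, chi)
      ws <- clo - tss0; we <- chi - tss0
    } else {
      # rel position x maps to genomic tss0 - x; rel in [ws,we) covers
      # genomic (tss0 - we, tss0 - ws]
      lo <- tss0 - window[2] + 1L; hi <- tss0 - window[1] + 1L # [lo, hi)
      clo <- max(lo, 0L); chi <- min(hi, L)
      seq <- revcomp_chr(substr(contig, clo + 1L, chi))
      ws <- tss0 - chi + 1L; we <- tss0 - clo + 1L
    }
    out[[i]] <- data.frame(gene_id = g$gene_id, strand = g$strand,
                           tss_genomic = tss0, win_start = ws, win_end = we,
                           truncated = (ws != window[1] || we != window[2]),
                           sequence = seq, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene_id = character(0),
                                      strand = character(0),
                                      tss_genomic = integer(0),
                                      win_start = integer(0),
                                      win_end = integer(0),
                                      truncated = logical(0),
                                      sequence = character(0))
  rownames(res) <- NULL
  res
}

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 file; features of type `gene` are used and the gene id is
#'   taken from the `ID` attribute.
#' @return data.frame with `gene_id`, `seqid`, `start`, `end`, `strand`.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$ID,
             seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write promoter regions as FASTA
#' @param promoters data.frame from [extract_promoters()].
#' @param path output FASTA.
#' @export
write_promoters_fasta <- function(promoters, path) {
  headers <- sprintf("%s strand=%s window=[%d,%d)%s",
                     promoters$gene_id, promoters$strand,
                     promoters$win_start, promoters$win_end,
                     ifelse(promoters$truncated, " truncated", ""))
  x <- Biostrings::DNAStringSet(promoters$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Scan promoters for IUPAC motifs on both strands
#'
#' Reports every (overlapping) occurrence of each motif and of its reverse
#' complement on the gene-oriented promoter sequence. Positions are
#' TSS-relative offsets of the leftmost base of the matched span on the gene
#' strand. An `N` in the sequence never matches. Palindromic spans that match
#' on both strands are reported once, on the + strand. Rows are ordered by
#' gene, position, motif.
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param motifs motif definition table with columns `name`, `iupac` (rows
#'   with `NA` iupac raise an error).
#' @return data.frame with `gene_id`, `motif`, `position`, `strand`.
#' @export
scan_motifs <- function(promoters, motifs) {
  stopifnot(all(c("name", "iupac") %in% names(motifs)))
  if (any(is.na(motifs$iupac)))
    stop("motif(s) without IUPAC string: ",
         paste(motifs$name[is.na(motifs$iupac)], collapse = ", "))
  for (iu in motifs$iupac) iupac_to_regex(iu)   # validate at load
  out <- list()
  for (i in seq_len(nrow(promoters))) {
    s <- promoters$sequence[i]
    off <- promoters$win_start[i]
    for (m in seq_len(nrow(motifs))) {
      iu <- motifs$iupac[m]
      fwd <- iupac_match_starts(s, iu)
      rev <- iupac_match_starts(s, revcomp_chr(iu))
      rev <- setdiff(rev, fwd)                  # palindromic span: keep +
      if (length(fwd) + length(rev) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        gene_id = promoters$gene_id[i], motif = motifs$name[m],
        position = c(fwd, rev) + off - 1L,
        strand = rep(c("+", "-"), c(length(fwd), length(rev))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$position, res$motif, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Positional enrichment of motifs among upregulated genes
#'
#' For each motif and window, counts genes with at least one hit inside the
#' window and tests foreground (upregulated) against background (all
#' expressed) genes with a one-sided hypergeometric test. The score is
#' `-log10(p)`; `high_score` flags motifs with `p < p_threshold` in either
#' designated window (the regions around -500 and the core promoter).
#'
#' @param hits motif hits from [scan_motifs()].
#' @param foreground upregulated gene ids (must be a subset of `background`).
#' @param background all expressed gene ids.
#' @param windows named list of TSS-relative half-open intervals; default
#'   `around-500` = `[-650, -350)` and `core` = `[-150, +50)`.
#' @param p_threshold flag threshold.
#' @return data.frame with one row per motif x window: hit/gene counts,
#'   `p`, `score`, `high_score`.
#' @export
positional_enrichment <- function(hits, foreground, background,
                                  windows = list(`around-500` = c(-650, -350),
                                                 core = c(-150, 50)),
                                  p_threshold = 0.01) {
  if (!length(foreground)) stop("empty foreground gene set")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  N <- length(background)
  n_fg <- length(foreground)
  out <- list()
  for (m in unique(hits$motif)) {
    hm <- hits[hits$motif == m & hits$gene_id %in% background, , drop = FALSE]
    for (w in names(windows)) {
      win <- windows[[w]]
      inw <- hm[hm$position >= win[1] & hm$position < win[2], , drop = FALSE]
      genes_hit <- unique(inw$gene_id)
      K <- length(genes_hit)
      k <- length(intersect(genes_hit, foreground))
      p <- stats::phyper(k - 1, K, N - K, n_fg, lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        motif = m, window = w,
        fg_hit_genes = k, fg_genes = n_fg,
        bg_hit_genes = K, bg_genes = N,
        p = p, score = -log10(max(p, .Machine$double.xmin)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(motif = character(0), window = character(0),
                      fg_hit_genes = integer(0), fg_genes = integer(0),
                      bg_hit_genes = integer(0), bg_genes = integer(0),
                      p = numeric(0), score = numeric(0),
                      high_score = logical(0)))
  flagged <- tapply(res$p < p_threshold, res$motif, any)
  res$high_score <- as.logical(flagged[res$motif])
  rownames(res) <- NULL
  res
}

#' Motif copy density and density class for one gene
#'
#' Counts hits of one motif whose 5'-most base lies inside the window (either
#' strand) and assigns the density class: `low` below 8 copies, `high` for
#' 8-10, `very_high` for 11 or more.
#'
#' @param hits motif hits for one gene (as from [scan_motifs()]).
#' @param motif motif name.
#' @param window counting window, default `c(-1200, 500)`.
#' @return list with `count` and `class`.
#' @export
motif_density <- function(hits, motif, window = c(-1200, 500)) {
  h <- hits[hits$motif == motif & hits$position >= window[1] &
              hits$position < window[2], , drop = FALSE]
  n <- nrow(h)
  cls <- if (n >= 11) "very_high" else if (n >= 8) "high" else "low"
  list(count = n, class = cls)
}

#' Density classes for a set of genes
#'
#' @param hits motif hits from [scan_motifs()].
#' @param genes gene ids to classify (genes without hits get count 0).
#' @param motif motif name.
#' @param window counting window.
#' @return data.frame `gene_id`, `motif`, `count`, `class`.
#' @export
density_classes <- function(hits, genes, motif, window = c(-1200, 500)) {
  res <- data.frame(gene_id = genes, motif = motif, count = 0L,
                    class = "low", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    d <- motif_density(hits[hits$gene_id == genes[i], , drop = FALSE],
                       motif, window)
    res$count[i] <- d$count
    res$class[i] <- d$class
  }
  res
}

#' Spatial cis-element map table
#'
#' Per-gene ordered track of in-window motif occurrences, suitable for
#' plotting spatial maps. Genes without any hit keep an empty track (zero
#' rows but present in the `genes` attribute); genes without an extracted
#' promoter are omitted with a message when `promoters` is supplied.
#'
#' @param hits motif hits from [scan_motifs()].
#' @param genes gene ids to include.
#' @param window display window, default `c(-1200, 500)`.
#' @param promoters optional promoter table used to drop genes that have no
#'   promoter region.
#' @return data.frame `gene_id`, `position`, `motif`, `strand`, sorted by
#'   gene then position; attribute `"genes"` lists all requested genes with a
#'   promoter.
#' @export
spatial_map <- function(hits, genes, window = c(-1200, 500),
                        promoters = NULL) {
  if (!is.null(promoters)) {
    absent <- setdiff(genes, promoters$gene_id)
    if (length(absent)) {
      message("spatial_map: omitting ", length(absent),
              " gene(s) without a promoter")
      genes <- setdiff(genes, absent)
    }
  }
  h <- hits[hits$gene_id %in% genes & hits$position >= window[1] &
              hits$position < window[2], , drop = FALSE]
  h <- h[order(h$gene_id, h$position, h$motif), c("gene_id", "position",
                                                  "motif", "strand")]
  rownames(h) <- NULL
  attr(h, "genes") <- genes
  attr(h, "window") <- window
  h
}
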