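# Ortholog pairing from transcript-vs-gene-model alignment hit tables:
# longest alignment per query, then most-stable mapping per target.

#' Pick the best alignment target for one query locus
#'
#' Implements the longest-alignment rule: the hit with maximal alignment
#' length wins; ties go to higher identity, then to the lexicographically
#' smallest target id.
#'
#' @param hits data.frame with columns `query_id`, `target_id`, `aln_length`,
#'   `identity`, `query_coverage`, all rows sharing one `query_id`.
#' @return the selected row (one-row data.frame), or `NULL` for an empty
#'   table (no-pair signal).
#' @export
select_best_target <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  if (length(unique(hits$query_id)) != 1)
    stop("select_best_target expects hits for a single query")
  o <- order(-hits$aln_length, -hits$identity, hits$target_id)
  hits[o[1], , drop = FALSE]
}

#' Resolve many-to-one ortholog claims
#'
#' When several query loci claim the same target locus, the pair with the
#' most stable mapping is kept, operationalized as
#' `stability = identity * query_coverage`; ties go to longer alignment,
#' then to the smallest query id. The result is a one-to-one map.
#'
#' @param pairs data.frame of best-per-query pairs with columns `locus_a`,
#'   `locus_b`, `aln_length`, `identity`, `query_coverage`.
#' @return data.frame of retained pairs with an added `stability` column.
#' @export
resolve_many_to_one <- function(pairs) {
  if (nrow(pairs) == 0) return(cbind(pairs, stability = numeric(0)))
  if (anyDuplicated(pairs$locus_a)) stop("pairs must be best-per-query already")
  pairs$stability <- pairs$identity * pairs$query_coverage
  o <- order(pairs$locus_b, -pairs$stability, -pairs$aln_length, pairs$locus_a)
  p <- pairs[o, , drop = FALSE]
  keep <- !duplicated(p$locus_b)
  out <- p[keep, , drop = FALSE]
  out[order(out$locus_a), , drop = FALSE]
}

#' Build a one-to-one ortholog map from an alignment hit table
#'
#' Applies [select_best_target()] per query then [resolve_many_to_one()].
#'
#' @param hits data.frame of alignment hits (columns as in
#'   [select_best_target()]).
#' @return one-to-one data.frame with columns `locus_a`, `locus_b`,
#'   `aln_length`, `identity`, `query_coverage`, `stability`.
#' @export
build_ortholog_map <- function(hits) {
  cols <- c("query_id", "target_id", "aln_length", "identity", "query_coverage")
  stopifnot(all(cols %in% names(hits)))
  best <- do.call(rbind, lapply(split(hits, hits$query_id), select_best_target))
  if (is.null(best) || nrow(best) == 0)
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      aln_length = numeric(0), identity = numeric(0),
                      query_coverage = numeric(0), stability = numeric(0)))
  pairs <- data.frame(locus_a = best$query_id, locus_b = best$target_id,
                      aln_length = best$aln_length, identity = best$identity,
                      query_coverage = best$query_coverage,
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  resolve_many_to_one(pairs)
}

#' Read an alignment hit table from TSV
#'
#' Columns: query, target, aln_length, identity, coverage (header row with
#' these names or the canonical `query_id`/`target_id`/`query_coverage`).
#' @param path TSV file.
#' @return normalized data.frame of hits.
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ren <- c(query = "query_id", target = "target_id", coverage = "query_coverage")
  for (nm in names(ren)) if (nm %in% names(df) && !(ren[[nm]] %in% names(df)))
    names(df)[names(df) == nm] <- ren[[nm]]
  cols <- c("query_id", "target_id", "aln_length", "identity", "query_coverage")
  stopifnot(all(cols %in% names(df)))
  df[cols]
}

#' Write ortholog pairs as TSV
#' @param pairs data.frame from [build_ortholog_map()].
#' @param path output file.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Toy exact-seed aligner for synthetic sequences
#'
#' Deterministic k-mer-seeded ungapped aligner used as plumbing to produce
#' alignment hit tables from synthetic transcripts: for every query/target
#' pair sharing at least one exact k-mer, the best diagonal (most shared
#' k-mers) is extended ungapped across the full overlap and summarized as one
#' hit.
#'
#' @param query_seqs named character vector of query sequences (ACGT).
#' @param target_seqs named character vector of target sequences.
#' @param k seed length, `>= 8`.
#' @return data.frame of hits with columns `query_id`, `target_id`,
#'   `aln_length`, `identity`, `query_coverage`.
#' @export
toy_align <- function(query_seqs, target_seqs, k = 11) {
  stopifnot(k >= 8)
  if (length(query_seqs) == 0 || length(target_seqs) == 0)
    return(data.frame(query_id = character(0), target_id = character(0),
                      aln_length = integer(0), identity = numeric(0),
                      query_coverage = numeric(0)))
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }
  # target k-mer index: kmer -> list of (target index, position)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(target_seqs)) {
    km <- kmers(target_seqs[[j]])
    for (p in seq_along(km)) {
      key <- km[p]
      index[[key]] <- rbind(if (!is.null(index[[key]])) index[[key]],
                            c(j, p))
    }
  }
  out <- list()
  for (i in seq_along(query_seqs)) {
    qs <- query_seqs[[i]]
    qk <- kmers(qs)
    # diagonals per target: offset = target_pos - query_pos
    diags <- list()
    for (p in seq_along(qk)) {
      hit <- index[[qk[p]]]
      if (is.null(hit)) next
      for (r in seq_len(nrow(hit))) {
        key <- paste(hit[r, 1], hit[r, 2] - p, sep = ":")
        diags[[key]] <- c(diags[[key]], p)
      }
    }
    if (!length(diags)) next
    # strongest diagonal per target
    tgt <- vapply(strsplit(names(diags), ":", fixed = TRUE), `[`, "", 1)
    for (j in unique(tgt)) {
      keys <- names(diags)[tgt == j]
      best <- keys[which.max(vapply(diags[keys], length, 0L))]
      off <- as.integer(strsplit(best, ":", fixed = TRUE)[[1]][2])
      ts <- target_seqs[[as.integer(j)]]
      # ungapped extension over the full overlap of the two sequences
      qstart <- max(1L, 1L - off)
      tstart <- qstart + off
      len <- min(nchar(qs) - qstart, nchar(ts) - tstart) + 1L
      qb <- strsplit(substr(qs, qstart, qstart + len - 1L), "", fixed = TRUE)[[1]]
      tb <- strsplit(substr(ts, tstart, tstart + len - 1L), "", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- data.frame(
        query_id = names(query_seqs)[i],
        target_id = names(target_seqs)[as.integer(j)],
        aln_length = len,
        identity = mean(qb == tb),
        query_coverage = len / nchar(qs),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(query_id = character(0), target_id = character(0),
                      aln_length = integer(0), identity = numeric(0),
                      query_coverage = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$query_id, res$target_id), , drop = FALSE]
}
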