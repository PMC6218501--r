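# Count matrix container: genes x samples integer counts plus sample metadata.

#' Construct a count matrix
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param samples data.frame with one row per column of `counts` and at least
#'   the columns `sample`, `genotype`, `timepoint_hr`, `replicate`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), is.data.frame(samples),
            ncol(counts) == nrow(samples),
            all(c("sample", "genotype", "timepoint_hr", "replicate") %in%
                  names(samples)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  genotypes:", paste(unique(x$samples$genotype), collapse = ", "), "\n")
  cat("  timepoints (h):", paste(sort(unique(x$samples$timepoint_hr)),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write counts as TSV
#'
#' First column `gene_id`, one column per sample.
#' @param x a `count_matrix`.
#' @param path output file.
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read counts from TSV
#'
#' Expects a `gene_id` column and sample columns named
#' `genotype_t<hours>_r<replicate>` as written by [write_counts_tsv()].
#' @param path TSV file.
#' @return a `count_matrix`.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("gene_id" %in% names(df))
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  parts <- strsplit(colnames(m), "_", fixed = TRUE)
  ok <- lengths(parts) == 3
  if (!all(ok)) stop("sample columns must be named genotype_t<h>_r<rep>")
  samples <- data.frame(
    sample = colnames(m),
    genotype = vapply(parts, `[`, "", 1),
    timepoint_hr = as.numeric(sub("^t", "", vapply(parts, `[`, "", 2))),
    replicate = as.integer(sub("^r", "", vapply(parts, `[`, "", 3))),
    stringsAsFactors = FALSE)
  count_matrix(m, samples)
}
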