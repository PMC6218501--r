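# Expression analysis: median-of-ratios normalization, method-of-moments
# dispersion with shrinkage, per-timepoint NB likelihood-ratio DE tests,
# response classification, cross-species concordance, and TF family
# saturation summaries.

#' Median-of-ratios normalization
#'
#' Size factors are the per-sample median of count ratios to the geometric
#' mean reference, computed over genes with all-positive counts and rescaled
#' to geometric mean 1 (which makes normalization idempotent); normalized
#' values are `count / size_factor`. If no gene has all-positive counts the
#' function falls back to total-count scaling (factors proportional to
#' library totals, geometric mean 1) with a warning.
#'
#' @param x a [count_matrix()] or a bare counts matrix.
#' @return list with `normalized` (matrix) and `size_factors`.
#' @export
normalize_counts <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  if (any(colSums(counts) <= 0)) stop("every sample must have positive total")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene with all-positive counts; falling back to total-count scaling")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  } else {
    ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
      stats::median(col / ref))
    sf <- sf / exp(mean(log(sf)))
  }
  list(normalized = sweep(counts, 2, sf, `/`), size_factors = sf)
}

#' Method-of-moments NB dispersion with shrinkage
#'
#' For each gene, `alpha = max(0, (s^2 - m) / m^2)` is computed from
#' normalized counts within each replicated genotype-by-timepoint condition,
#' averaged across conditions with positive mean, then shrunk 50/50 toward
#' the genome-wide median of the raw estimates. With no replicated condition
#' a single global estimate from cross-timepoint pooling is used for all
#' genes (with a warning).
#'
#' @param x a [count_matrix()].
#' @param size_factors optional precomputed size factors.
#' @return named per-gene dispersion vector; the raw (unshrunk) estimates are
#'   attached as attribute `"raw"`.
#' @export
estimate_dispersion <- function(x, size_factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(size_factors)) size_factors <- normalize_counts(x)$size_factors
  y <- sweep(x$counts, 2, size_factors, `/`)
  grp <- interaction(x$samples$genotype, x$samples$timepoint_hr, drop = TRUE)
  rep_grps <- names(which(table(grp) >= 2))
  if (!length(rep_grps)) {
    warning("no replicated condition; using a pooled global dispersion")
    m <- rowMeans(y); v <- apply(y, 1, stats::var)
    raw <- pmax(0, (v - m) / m^2)
    a <- stats::median(raw[is.finite(raw)], na.rm = TRUE)
    out <- rep(a, nrow(y)); names(out) <- rownames(y)
    attr(out, "raw") <- out
    return(out)
  }
  per_cond <- sapply(rep_grps, function(g) {
    cols <- which(grp == g)
    m <- rowMeans(y[, cols, drop = FALSE])
    v <- apply(y[, cols, drop = FALSE], 1, stats::var)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- NA
    pmax(0, a)
  })
  raw <- rowMeans(per_cond, na.rm = TRUE)
  raw[!is.finite(raw)] <- 0
  med <- stats::median(raw, na.rm = TRUE)
  out <- 0.5 * raw + 0.5 * med
  names(out) <- rownames(y)
  attr(out, "raw") <- raw
  out
}

# NB log-likelihood (continuous-y extension) at means mu * s, dispersion a.
# y, mu: genes x samples matrix / per-gene vector; s: per-sample factors.
#' @noRd
nb_loglik_rows <- function(y, mu, s, alpha) {
  muj <- outer(mu, s)
  if (length(alpha) == 1) alpha <- rep(alpha, length(mu))
  ll <- numeric(length(mu))
  pois <- alpha <= 1e-12
  if (any(pois)) {
    m <- muj[pois, , drop = FALSE]
    yy <- y[pois, , drop = FALSE]
    ll[pois] <- rowSums(yy * log(pmax(m, 1e-300)) - m - lgamma(yy + 1))
  }
  if (any(!pois)) {
    a <- alpha[!pois]
    m <- muj[!pois, , drop = FALSE]
    yy <- y[!pois, , drop = FALSE]
    r <- 1 / a
    am <- m * a
    ll[!pois] <- rowSums(lgamma(yy + r) - lgamma(r) - lgamma(yy + 1) +
                           yy * log(pmax(am / (1 + am), 1e-300)) -
                           r * log1p(am))
  }
  ll
}

# Per-gene NB mean MLE with sample factors s and fixed dispersion, by Newton
# iteration on log(mu), vectorized across genes. Exact closed form when all
# factors are equal or alpha = 0.
#' @noRd
nb_mean_mle <- function(y, s, alpha) {
  mu <- pmax(rowSums(y) / sum(s), 1e-8)
  if (all(abs(s - s[1]) < 1e-12) || all(alpha <= 1e-12)) return(mu)
  if (length(alpha) == 1) alpha <- rep(alpha, nrow(y))
  for (it in 1:25) {
    den <- 1 + outer(alpha * mu, s)          # 1 + a*mu*s
    g <- rowSums(y) / mu -
      rowSums(sweep(y + 1 / alpha, 2, s, `*`) * (alpha / den) *
                matrix(1, nrow(y), ncol(y)))
    # derivative of score wrt mu
    h <- -rowSums(y) / mu^2 +
      rowSums(sweep((y + 1 / alpha), 2, s^2, `*`) * (alpha^2 / den^2))
    step <- g / h
    step[!is.finite(step)] <- 0
    mu_new <- pmax(mu - step, 1e-8)
    if (max(abs(mu_new - mu) / pmax(mu, 1)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  mu
}

#' Per-timepoint NB likelihood-ratio differential expression test
#'
#' For each gene, compares a stress timepoint against 0 h within one
#' genotype: log2 fold change of normalized means with pseudocount 0.5, and
#' a likelihood-ratio p-value from nested NB fits (shared mean vs separate
#' means, plug-in dispersion), chi-squared with 1 df. All-zero genes get
#' `log2fc = 0, p = 1`.
#'
#' @param x a [count_matrix()].
#' @param genotype genotype to test.
#' @param timepoint_hr stress timepoint (compared against 0 h).
#' @param dispersion per-gene (or scalar) NB dispersion; estimated with
#'   [estimate_dispersion()] when `NULL`.
#' @param size_factors optional size factors; computed when `NULL`.
#' @param pseudocount added to both normalized means in the fold change.
#' @return data.frame with `gene_id`, `log2fc`, `p`.
#' @export
de_test <- function(x, genotype, timepoint_hr, dispersion = NULL,
                    size_factors = NULL, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(size_factors)) size_factors <- normalize_counts(x)$size_factors
  if (is.null(dispersion)) dispersion <- estimate_dispersion(x, size_factors)
  sel0 <- x$samples$genotype == genotype & x$samples$timepoint_hr == 0
  selt <- x$samples$genotype == genotype & x$samples$timepoint_hr == timepoint_hr
  if (!any(sel0) || !any(selt))
    stop("need replicates at both 0 h and ", timepoint_hr, " h for genotype ", genotype)
  y0 <- x$counts[, sel0, drop = FALSE]; s0 <- size_factors[sel0]
  yt <- x$counts[, selt, drop = FALSE]; st <- size_factors[selt]
  a <- if (length(dispersion) == 1) rep(dispersion, nrow(y0)) else
    dispersion[rownames(y0)]
  m0 <- rowMeans(sweep(y0, 2, s0, `/`))
  mt <- rowMeans(sweep(yt, 2, st, `/`))
  log2fc <- log2((mt + pseudocount) / (m0 + pseudocount))
  mu0 <- nb_mean_mle(y0, s0, a)
  mut <- nb_mean_mle(yt, st, a)
  mus <- nb_mean_mle(cbind(y0, yt), c(s0, st), a)
  ll_alt <- nb_loglik_rows(y0, mu0, s0, a) + nb_loglik_rows(yt, mut, st, a)
  ll_null <- nb_loglik_rows(cbind(y0, yt), mus, c(s0, st), a)
  lrt <- pmax(0, 2 * (ll_alt - ll_null))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  zero <- rowSums(y0) + rowSums(yt) == 0
  log2fc[zero] <- 0; p[zero] <- 1
  data.frame(gene_id = rownames(y0), log2fc = log2fc, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full per-genotype DE table over all stress timepoints
#'
#' @inheritParams de_test
#' @return data.frame `gene_id`, `log2fc_1..T`, `p_1..T` (columns indexed by
#'   stress timepoint order); stress timepoints stored in attribute
#'   `"timepoints_hr"`.
#' @export
de_table <- function(x, genotype, dispersion = NULL, size_factors = NULL,
                     pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(size_factors)) size_factors <- normalize_counts(x)$size_factors
  if (is.null(dispersion)) dispersion <- estimate_dispersion(x, size_factors)
  tps <- sort(setdiff(unique(
    x$samples$timepoint_hr[x$samples$genotype == genotype]), 0))
  out <- NULL
  for (i in seq_along(tps)) {
    r <- de_test(x, genotype, tps[i], dispersion, size_factors, pseudocount)
    if (is.null(out)) out <- data.frame(gene_id = r$gene_id,
                                        stringsAsFactors = FALSE)
    out[[paste0("log2fc_", i)]] <- r$log2fc
    out[[paste0("p_", i)]] <- r$p
  }
  attr(out, "timepoints_hr") <- tps
  out
}

#' Classify genes as up, down or unchanged
#'
#' A gene is `up` if any timepoint has `log2fc > lfc_threshold` with
#' `p < p_threshold`, `down` for the mirrored rule; a gene with significant
#' events in both directions takes the class of its largest-|log2fc| event;
#' otherwise `unchanged`.
#'
#' @param de DE table from [de_table()].
#' @param lfc_threshold |log2 fold change| threshold (default 2, i.e.
#'   four-fold).
#' @param p_threshold raw p-value threshold (default 0.01).
#' @return named character vector of classes, one per gene.
#' @export
classify_response <- function(de, lfc_threshold = 2, p_threshold = 0.01) {
  lfc_cols <- grep("^log2fc_", names(de), value = TRUE)
  p_cols <- sub("^log2fc_", "p_", lfc_cols)
  stopifnot(all(p_cols %in% names(de)))
  lfc <- as.matrix(de[lfc_cols])
  p <- as.matrix(de[p_cols])
  sig <- p < p_threshold & abs(lfc) > lfc_threshold
  eff <- abs(lfc) * sig
  cls <- rep("unchanged", nrow(de))
  any_sig <- rowSums(sig) > 0
  if (any(any_sig)) {
    best <- max.col(eff[any_sig, , drop = FALSE], ties.method = "first")
    sgn <- lfc[any_sig, , drop = FALSE][cbind(seq_len(sum(any_sig)), best)]
    cls[any_sig] <- ifelse(sgn > 0, "up", "down")
  }
  names(cls) <- de$gene_id
  cls
}

#' Cross-species concordance over ortholog pairs
#'
#' Builds the 3x3 contingency of response classes across ortholog pairs and
#' the directional percentages (fraction of genotype-A upregulated genes
#' whose ortholog is also upregulated in B, and the reverse; likewise for
#' downregulated).
#'
#' @param classes_a,classes_b named class vectors from [classify_response()].
#' @param pairs data.frame with columns `gene_a`/`locus_a` and
#'   `gene_b`/`locus_b`.
#' @return object of class `concordance_table`: list with `table` (3x3
#'   counts), `percent` (directional percentages), `n_pairs` classified and
#'   `n_excluded` pairs missing a class.
#' @export
ortholog_concordance <- function(classes_a, classes_b, pairs) {
  ca_col <- intersect(c("gene_a", "locus_a"), names(pairs))[1]
  cb_col <- intersect(c("gene_b", "locus_b"), names(pairs))[1]
  if (is.na(ca_col) || is.na(cb_col)) stop("pairs must name both loci")
  if (nrow(pairs) == 0) {
    warning("empty ortholog pair list")
    lv <- c("up", "down", "unchanged")
    return(structure(list(table = table(factor(character(0), lv),
                                        factor(character(0), lv)),
                          percent = c(up_a_in_b = NA, up_b_in_a = NA,
                                      down_a_in_b = NA, down_b_in_a = NA),
                          n_pairs = 0L, n_excluded = 0L),
                     class = "concordance_table"))
  }
  a <- classes_a[pairs[[ca_col]]]
  b <- classes_b[pairs[[cb_col]]]
  ok <- !is.na(a) & !is.na(b)
  lv <- c("up", "down", "unchanged")
  tab <- table(A = factor(a[ok], lv), B = factor(b[ok], lv))
  pct <- c(
    up_a_in_b = 100 * tab["up", "up"] / max(1, sum(tab["up", ])),
    up_b_in_a = 100 * tab["up", "up"] / max(1, sum(tab[, "up"])),
    down_a_in_b = 100 * tab["down", "down"] / max(1, sum(tab["down", ])),
    down_b_in_a = 100 * tab["down", "down"] / max(1, sum(tab[, "down"])))
  structure(list(table = tab, percent = pct, n_pairs = sum(ok),
                 n_excluded = sum(!ok)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Ortholog response-class concordance (", x$n_pairs, " pairs, ",
      x$n_excluded, " excluded)\n", sep = "")
  print(x$table)
  cat(sprintf("up A->B: %.1f%%  up B->A: %.1f%%  down A->B: %.1f%%  down B->A: %.1f%%\n",
              x$percent["up_a_in_b"], x$percent["up_b_in_a"],
              x$percent["down_a_in_b"], x$percent["down_b_in_a"]))
  invisible(x)
}

#' Transcription-factor family saturation summary
#'
#' Sums normalized expression per timepoint within each family and reports
#' the maximum fold-induction of the cumulative curve over its 0 h value
#' (pseudocount 0.5).
#'
#' @param normalized genes x samples normalized matrix.
#' @param timepoint_hr per-sample timepoints.
#' @param family named character vector mapping gene id to family (`NA` or
#'   missing genes are ignored; each gene belongs to at most one family).
#' @return data.frame with one row per family: cumulative expression per
#'   timepoint and `max_fold_induction`.
#' @export
family_saturation <- function(normalized, timepoint_hr, family) {
  fam <- family[!is.na(family)]
  fam <- fam[names(fam) %in% rownames(normalized)]
  if (!length(fam)) { warning("no annotated family member present");
    return(data.frame(family = character(0))) }
  tps <- sort(unique(timepoint_hr))
  per_tp <- sapply(tps, function(t)
    rowMeans(normalized[, timepoint_hr == t, drop = FALSE]))
  colnames(per_tp) <- paste0("t", tps)
  agg <- rowsum(per_tp[names(fam), , drop = FALSE], fam)
  if (!0 %in% tps) stop("timepoint 0 required for fold-induction")
  base <- agg[, "t0"]
  mfi <- apply(sweep(agg + 0.5, 1, base + 0.5, `/`), 1, max)
  data.frame(family = rownames(agg), agg, max_fold_induction = mfi,
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}
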