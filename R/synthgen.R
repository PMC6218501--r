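# Synthetic two-genotype cold-stress dataset generator with planted truth.
#
# Genotype A emulates the cold-tolerant wild donor carrying an intact
# hub-coupled regulon; genotype B carries the same regulon fragmented into
# uncorrelated temporal blocks. Counts are negative-binomial draws around
# latent log2 fold-change curves; promoters are motif-free backgrounds with
# cis-element copies planted at controlled densities and positions.

# Canonical temporal response shapes (multipliers of de_log2fc over the four
# stress timepoints). 1-4 upregulated, 5-8 the mirrored downregulated forms.
RESPONSE_SHAPES <- rbind(
  sustained  = c(0.70, 0.90, 1.00, 0.95),
  early      = c(1.00, 0.60, 0.30, 0.10),
  late       = c(0.10, 0.40, 0.80, 1.00),
  mid_peak   = c(0.35, 1.00, 0.60, 0.20)
)
RESPONSE_SHAPES <- rbind(RESPONSE_SHAPES, -RESPONSE_SHAPES)
rownames(RESPONSE_SHAPES)[5:8] <- paste0(rownames(RESPONSE_SHAPES)[1:4], "_down")

# Shared latent curve of the intact regulon: induction ramping to a 72 h peak
# with partial relaxation by 168 h, a typical sustained cold-response kinetic.
REGULON_BASE_SHAPE <- c(0.15, 0.55, 1.00, 0.70)

#' Configuration for the synthetic dataset generator
#'
#' @param n_genes number of genotype-A genes.
#' @param n_tf number of genes flagged as transcription factors (annotated
#'   with a family drawn from common rice TF families).
#' @param timepoints_hr sampling times in hours; must include 0. The default
#'   follows the 0/24/48/72/168 h cold time course.
#' @param n_replicates biological replicates per genotype and timepoint.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   `mu * (1 + alpha * mu)`); 0 switches the generator to deterministic
#'   rounded means (exact zero-noise limit, see Details).
#' @param lib_size_range range of library size factors; per-sample factors are
#'   drawn log-uniformly from it.
#' @param de_fraction fraction of genes that are differentially expressed.
#' @param de_log2fc planted peak |log2 fold change| of DE genes.
#' @param de_overlap fraction of genotype-A DE genes whose ortholog is planted
#'   with the same response direction in genotype B (cross-species
#'   concordance of the planted truth).
#' @param regulon_size number of hub-coupled regulon member genes (all
#'   cold-upregulated in both genotypes).
#' @param regulon_corr minimum pairwise correlation of regulon member latent
#'   profiles in genotype A, before count noise.
#' @param fragment_into number of mutually uncorrelated latent blocks the
#'   genotype-B regulon is split into (at most 3: the centered 4-point
#'   profile space has rank 3).
#' @param promoter_window TSS-relative half-open promoter window
#'   `[start, end)`, upstream negative.
#' @param motif_densities named numeric vector: motif name -> copies planted
#'   in each regulon member promoter.
#' @param plant_window TSS-relative window that receives the planted copies;
#'   the default sits around -500, inside the -1200..+500 density window.
#' @param motif_defs motif definition table used to resolve motif names to
#'   IUPAC strings (see [default_motifs()]).
#' @param paralog_fraction fraction of genes given a many-to-one ortholog
#'   (two A loci sharing one B locus).
#' @param seed integer seed; the full dataset is a pure function of the
#'   configuration including the seed.
#'
#' @details With `dispersion = 0` the generator emits `round(mu)` instead of
#'   random draws so that zero-noise datasets are exactly reproducible from
#'   the latent means; [simulate_counts()] with `dispersion = 0` draws
#'   Poisson, the distributional limit.
#'
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1000,
                         n_tf = 100,
                         timepoints_hr = c(0, 24, 48, 72, 168),
                         n_replicates = 3,
                         dispersion = 0.1,
                         lib_size_range = c(0.7, 1.4),
                         de_fraction = 0.3,
                         de_log2fc = 3,
                         de_overlap = 0.5,
                         regulon_size = 40,
                         regulon_corr = 0.95,
                         fragment_into = 3,
                         promoter_window = c(-3000, 2000),
                         motif_densities = c(BRRE = 9),
                         plant_window = c(-650, -350),
                         motif_defs = default_motifs(),
                         paralog_fraction = 0.05,
                         seed = 1) {
  stopifnot(n_genes >= 10, n_tf >= 0, n_tf <= n_genes,
            n_replicates >= 1, length(timepoints_hr) >= 2)
  if (!0 %in% timepoints_hr) stop("timepoints_hr must include 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  if (round(de_fraction * n_genes) < regulon_size)
    stop("regulon_size exceeds the DE budget (de_fraction * n_genes)")
  if (regulon_corr <= 0 || regulon_corr > 1) stop("regulon_corr must be in (0,1]")
  if (fragment_into < 1 || fragment_into > 3)
    stop("fragment_into must be between 1 and 3")
  stopifnot(length(promoter_window) == 2, promoter_window[1] < promoter_window[2],
            length(lib_size_range) == 2, all(lib_size_range > 0))
  if (plant_window[1] < promoter_window[1] || plant_window[2] > promoter_window[2])
    stop("plant_window must lie inside promoter_window")
  cfg <- list(n_genes = as.integer(n_genes), n_tf = as.integer(n_tf),
              timepoints_hr = sort(unique(timepoints_hr)),
              n_replicates = as.integer(n_replicates),
              dispersion = dispersion, lib_size_range = lib_size_range,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              de_overlap = de_overlap,
              regulon_size = as.integer(regulon_size),
              regulon_corr = regulon_corr,
              fragment_into = as.integer(fragment_into),
              promoter_window = as.integer(promoter_window),
              motif_densities = motif_densities,
              plant_window = as.integer(plant_window),
              motif_defs = motif_defs,
              paralog_fraction = paralog_fraction,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate negative-binomial counts for one gene
#'
#' Draws counts with mean `s_j * mu_t` and variance
#' `s_j * mu_t * (1 + alpha * s_j * mu_t)`; `alpha = 0` degenerates to
#' Poisson. `size_factors` must be a whole number of replicates per
#' timepoint; samples are ordered replicate-within-timepoint.
#'
#' @param mean_profile non-negative per-timepoint means.
#' @param dispersion NB dispersion alpha, `>= 0`.
#' @param size_factors per-sample library size factors.
#' @param seed optional seed (RNG state restored afterwards).
#' @return integer count vector, one entry per size factor.
#' @export
simulate_counts <- function(mean_profile, dispersion, size_factors, seed = NULL) {
  if (any(!is.finite(mean_profile)) || any(mean_profile < 0))
    stop("mean_profile must be finite and non-negative")
  if (dispersion < 0) stop("dispersion must be >= 0")
  nt <- length(mean_profile)
  if (length(size_factors) %% nt != 0L)
    stop("length(size_factors) must be a multiple of length(mean_profile)")
  nrep <- length(size_factors) %/% nt
  mu <- rep(mean_profile, each = nrep) * size_factors
  with_seed(seed, {
    if (dispersion == 0) {
      y <- stats::rpois(length(mu), mu)
    } else {
      y <- stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      y[mu == 0] <- 0L
    }
    as.integer(y)
  })
}

#' Plant motif copies into a promoter sequence
#'
#' Inserts `n_copies` non-overlapping instances of an IUPAC motif at uniform
#' random positions inside a TSS-relative window, instantiating degenerate
#' positions uniformly at random.
#'
#' @param sequence promoter sequence (bases).
#' @param motif IUPAC motif string.
#' @param n_copies number of copies to plant.
#' @param window TSS-relative half-open interval `[start, end)` receiving the
#'   copies.
#' @param seed optional seed.
#' @param seq_window TSS-relative window spanned by `sequence` (position 1 of
#'   the string is `seq_window[1]`).
#' @return the modified sequence.
#' @export
plant_motifs <- function(sequence, motif, n_copies, window,
                         seed = NULL, seq_window = c(-3000, 2000)) {
  if (n_copies == 0) return(sequence)
  L <- nchar(sequence)
  if (L != seq_window[2] - seq_window[1])
    stop("sequence length does not match seq_window")
  if (window[1] < seq_window[1] || window[2] > seq_window[2])
    stop("window does not fit inside the sequence")
  w <- nchar(motif)
  # string indices (1-based) eligible as motif starts
  lo <- window[1] - seq_window[1] + 1L
  hi <- window[2] - seq_window[1] - w + 1L
  if (hi < lo || n_copies * w > (window[2] - window[1]))
    stop("window too small for ", n_copies, " copies of ", motif)
  with_seed(seed, {
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_copies) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place non-overlapping copies")
      cand <- sample(lo:hi, 1L)
      if (!any(abs(cand - starts) < w)) starts <- c(starts, cand)
    }
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    mot <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
    for (s in starts) {
      inst <- vapply(mot, function(code) {
        opts <- strsplit(IUPAC_MAP[[code]], "", fixed = TRUE)[[1]]
        if (length(opts) == 1L) opts else sample(opts, 1L)
      }, character(1))
      ch[s:(s + w - 1L)] <- inst
    }
    paste(ch, collapse = "")
  })
}

# Random ACGT background guaranteed free of the given motifs on both strands.
# Accidental occurrences are patched by redrawing the matched span until the
# sequence is clean, so planted densities are exact counts.
#' @noRd
motif_free_background <- function(len, forbid_iupac) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  pats <- unique(c(forbid_iupac, revcomp_chr(forbid_iupac)))
  for (iter in 1:200) {
    s <- paste(ch, collapse = "")
    dirty <- FALSE
    for (p in pats) {
      st <- iupac_match_starts(s, p)
      if (length(st)) {
        dirty <- TRUE
        w <- nchar(p)
        for (x in st) ch[x:(x + w - 1L)] <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
      }
    }
    if (!dirty) return(s)
  }
  stop("failed to generate a motif-free background")
}

# Latent curves for the fragmented genotype-B regulon: mutually uncorrelated
# by construction (orthogonalized centered random curves, affinely rescaled
# to peak at de_log2fc).
#' @noRd
fragment_block_curves <- function(k, de_log2fc) {
  nt <- length(REGULON_BASE_SHAPE)
  repeat {
    m <- matrix(stats::rnorm(nt * k), nt, k)
    m <- sweep(m, 2, colMeans(m))
    q <- qr(m)
    if (q$rank == k) { m <- qr.Q(q)[, seq_len(k), drop = FALSE]; break }
  }
  m <- sweep(m, 2, colMeans(m))  # Q columns of centered matrix stay centered
  apply(m, 2, function(v) de_log2fc * (v - min(v)) / (max(v) - min(v)))
}

# Jittered copies of a base curve with all pairwise correlations >= rho.
#' @noRd
jittered_members <- function(base, n, rho) {
  sj <- sqrt(0.5 * stats::var(base) * (1 - rho) / rho)
  prof <- t(replicate(n, base + stats::rnorm(length(base), 0, sj)))
  if (n >= 2 && sj > 0) {
    for (iter in 1:500) {
      cc <- stats::cor(t(prof))
      if (min(cc) >= rho) break
      worst <- which.min(apply(cc, 1, min))
      prof[worst, ] <- base + stats::rnorm(length(base), 0, sj)
    }
  }
  prof
}

#' Generate a paired two-genotype synthetic dataset
#'
#' Produces replicated NB count matrices for both genotypes, a truthful
#' ortholog map with planted many-to-one cases, genotype-A promoter sequences
#' with motif copies planted in regulon members, and the full planted ground
#' truth. Identical configurations (including seed) give identical output.
#'
#' @param config a [synth_config()].
#' @return a list with elements `counts_a`, `counts_b` (class
#'   `count_matrix`), `orthologs` (data.frame `gene_a`, `gene_b`),
#'   `promoters` (data.frame as returned by [extract_promoters()]),
#'   `gene_info` (TF flag and family per genotype-A gene), and `truth`
#'   (planted DE sets, cluster labels, regulon membership and hub, fragmented
#'   blocks, motif placements).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    tp <- cfg$timepoints_hr
    nt_stress <- length(tp) - 1L
    stopifnot(nt_stress == length(REGULON_BASE_SHAPE))
    genes_a <- sprintf("GA%05d", seq_len(n))

    n_de <- round(cfg$de_fraction * n)
    n_reg <- cfg$regulon_size
    reg_idx <- seq_len(n_reg)
    other_de_idx <- if (n_de > n_reg) (n_reg + 1L):n_de else integer(0)
    shape_of <- integer(n)                       # 0 = flat / regulon
    if (length(other_de_idx))
      shape_of[other_de_idx] <- rep_len(seq_len(nrow(RESPONSE_SHAPES)),
                                        length(other_de_idx))

    # latent log2fc curves over stress timepoints, genotype A
    base_a <- REGULON_BASE_SHAPE * cfg$de_log2fc
    curves_a <- matrix(0, n, nt_stress)
    curves_a[reg_idx, ] <- jittered_members(base_a, n_reg, cfg$regulon_corr)
    for (i in other_de_idx)
      curves_a[i, ] <- RESPONSE_SHAPES[shape_of[i], ] * cfg$de_log2fc

    up_a <- genes_a[c(reg_idx, other_de_idx[shape_of[other_de_idx] <= 4])]
    down_a <- genes_a[other_de_idx[shape_of[other_de_idx] > 4]]

    # ortholog map with many-to-one cases among flat genes
    n_par <- min(round(cfg$paralog_fraction * n), (n - n_de) %/% 2)
    flat_idx <- if (n_de < n) (n_de + 1L):n else integer(0)
    par_src <- utils::head(flat_idx, n_par)          # keep their own ortholog
    par_dup <- utils::tail(flat_idx, n_par)          # share the partner's
    b_of <- integer(n)                               # index into B gene list
    keep_b <- setdiff(seq_len(n), par_dup)
    b_ids <- sprintf("GB%05d", seq_along(keep_b))
    b_of[keep_b] <- seq_along(keep_b)
    b_of[par_dup] <- b_of[par_src]
    orthologs <- data.frame(gene_a = genes_a, gene_b = b_ids[b_of],
                            stringsAsFactors = FALSE)

    # genotype-B planted truth: regulon members up in both genotypes but
    # fragmented; other DE genes concordant with probability de_overlap
    curves_b <- matrix(0, length(keep_b), nt_stress)
    blocks <- sort(rep_len(seq_len(cfg$fragment_into), n_reg))
    bc <- fragment_block_curves(cfg$fragment_into, cfg$de_log2fc)
    for (k in seq_len(cfg$fragment_into)) {
      mem <- reg_idx[blocks == k]
      curves_b[b_of[mem], ] <- jittered_members(bc[, k], length(mem),
                                                cfg$regulon_corr)
    }
    up_b <- orthologs$gene_b[reg_idx]
    down_b <- character(0)
    concord <- stats::runif(length(other_de_idx)) < cfg$de_overlap
    spare <- setdiff(flat_idx, par_dup)              # B-only DE donors
    for (j in seq_along(other_de_idx)) {
      i <- other_de_idx[j]
      sh <- shape_of[i]
      if (concord[j]) {
        curves_b[b_of[i], ] <- RESPONSE_SHAPES[sh, ] * cfg$de_log2fc
        if (sh <= 4) up_b <- c(up_b, orthologs$gene_b[i])
        else down_b <- c(down_b, orthologs$gene_b[i])
      } else if (length(spare)) {
        # keep the class sizes comparable: a flat A gene's ortholog takes
        # over the response in B
        i2 <- spare[1]; spare <- spare[-1]
        curves_b[b_of[i2], ] <- RESPONSE_SHAPES[sh, ] * cfg$de_log2fc
        if (sh <= 4) up_b <- c(up_b, orthologs$gene_b[i2])
        else down_b <- c(down_b, orthologs$gene_b[i2])
      }
    }

    # baseline abundances; regulon members kept well-expressed
    mu0_a <- stats::rlnorm(n, log(150), 0.6)
    mu0_a[reg_idx] <- stats::rlnorm(n_reg, log(200), 0.3)
    mu0_b <- stats::rlnorm(length(keep_b), log(150), 0.6)
    mu0_b[b_of[reg_idx]] <- stats::rlnorm(n_reg, log(200), 0.3)

    make_counts <- function(genotype, ids, mu0, curves) {
      nrep <- cfg$n_replicates
      ns <- length(tp) * nrep
      sf <- exp(stats::runif(ns, log(cfg$lib_size_range[1]),
                             log(cfg$lib_size_range[2])))
      mu_t <- cbind(mu0, mu0 * 2^curves)             # genes x timepoints
      mu <- mu_t[, rep(seq_along(tp), each = nrep), drop = FALSE]
      mu <- sweep(mu, 2, sf, `*`)
      y <- if (cfg$dispersion == 0) round(mu)
           else matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / cfg$dispersion),
                       nrow(mu), ncol(mu))
      storage.mode(y) <- "integer"
      samples <- data.frame(
        sample = paste(genotype, paste0("t", rep(tp, each = nrep)),
                       paste0("r", rep(seq_len(nrep), length(tp))), sep = "_"),
        genotype = genotype,
        timepoint_hr = rep(tp, each = nrep),
        replicate = rep(seq_len(nrep), length(tp)),
        size_factor_true = sf,
        stringsAsFactors = FALSE)
      dimnames(y) <- list(ids, samples$sample)
      count_matrix(y, samples)
    }
    counts_a <- make_counts("A", genes_a, mu0_a, curves_a)
    counts_b <- make_counts("B", b_ids, mu0_b, curves_b)

    # genotype-A promoters: motif-free background, copies planted in members
    forbid <- vapply(names(cfg$motif_densities), function(nm)
      motif_iupac(nm, cfg$motif_defs), character(1))
    pw <- cfg$promoter_window
    plen <- pw[2] - pw[1]
    seqs <- character(n)
    planted <- list()
    for (i in seq_len(n)) {
      s <- motif_free_background(plen, forbid)
      if (i %in% reg_idx) {
        for (m in seq_along(cfg$motif_densities)) {
          nm <- names(cfg$motif_densities)[m]
          s <- plant_motifs(s, forbid[m], cfg$motif_densities[[m]],
                            cfg$plant_window, seed = NULL, seq_window = pw)
          pos <- iupac_match_starts(s, forbid[m]) + pw[1] - 1L
          planted[[paste(genes_a[i], nm, sep = "|")]] <- pos
        }
      }
      seqs[i] <- s
    }
    promoters <- data.frame(gene_id = genes_a, strand = "+",
                            tss_genomic = NA_integer_,
                            win_start = pw[1], win_end = pw[2],
                            truncated = FALSE, sequence = seqs,
                            stringsAsFactors = FALSE)

    families <- c("bZIP", "NAC", "WRKY", "MYB", "AP2/ERF", "bHLH", "C2H2", "HSF")
    gene_info <- data.frame(gene_id = genes_a,
                            is_tf = seq_len(n) <= cfg$n_tf,
                            family = ifelse(seq_len(n) <= cfg$n_tf,
                                            rep_len(families, n), NA_character_),
                            stringsAsFactors = FALSE)

    cl <- shape_of[other_de_idx]
    names(cl) <- genes_a[other_de_idx]
    truth <- list(
      de_genes_by_genotype = list(A = list(up = up_a, down = down_a),
                                  B = list(up = unique(up_b),
                                           down = unique(down_b))),
      cluster_labels = cl,
      regulon_members = genes_a[reg_idx],
      hub_id = genes_a[1],
      fragmented_blocks = split(orthologs$gene_b[reg_idx], blocks),
      planted_motif_positions = planted,
      latent_log2fc_a = structure(curves_a, dimnames = list(genes_a, NULL)),
      latent_log2fc_b = structure(curves_b, dimnames = list(b_ids, NULL)),
      latent_mu0_a = stats::setNames(mu0_a, genes_a),
      latent_mu0_b = stats::setNames(mu0_b, b_ids))

    list(counts_a = counts_a, counts_b = counts_b, orthologs = orthologs,
         promoters = promoters, gene_info = gene_info, truth = truth,
         config = cfg)
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Counts as TSV (sample names encode genotype_timepoint_replicate),
#' promoters as FASTA with TSS-relative window in the header, orthologs as a
#' two-column TSV and the planted truth as JSON.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts_a = file.path(dir, "counts_A.tsv"),
             counts_b = file.path(dir, "counts_B.tsv"),
             orthologs = file.path(dir, "orthologs.tsv"),
             promoters = file.path(dir, "promoters_A.fasta"),
             truth = file.path(dir, "truth.json"))
  write_counts_tsv(dataset$counts_a, paths["counts_a"])
  write_counts_tsv(dataset$counts_b, paths["counts_b"])
  utils::write.table(dataset$orthologs, paths["orthologs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_promoters_fasta(dataset$promoters, paths["promoters"])
  tr <- dataset$truth
  tr$latent_log2fc_a <- NULL
  tr$latent_log2fc_b <- NULL
  tr$latent_mu0_a <- NULL
  tr$latent_mu0_b <- NULL
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
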