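# Negative-binomial model-based K-means over temporal expression profiles.
#
# Each cluster carries a relative temporal profile f_k (mean 1 across
# timepoints). A gene's fitted mean at sample j is a_g * f_k[t(j)], with the
# gene's abundance a_g re-estimated per candidate cluster, so clustering is
# driven by profile shape, not expression level. Assignment maximizes the NB
# log-likelihood at the gene's dispersion; profiles are re-estimated from the
# members; iteration stops when assignments are stable, the likelihood stops
# improving, or after max_iter rounds.

#' NB model-based K-means clustering of temporal profiles
#'
#' @param normalized genes x samples matrix of size-factor-adjusted counts.
#' @param timepoint_hr per-sample timepoints.
#' @param K number of clusters (default 8).
#' @param dispersion per-gene (or scalar) NB dispersion.
#' @param seed integer seed for the k-means++-style initialization.
#' @param max_iter iteration cap.
#' @return object of class `cluster_assignment`: list with `cluster` (named
#'   integer vector), `profiles` (K x timepoints relative profiles),
#'   `loglik` (trajectory, non-decreasing), `n_iterations`, `K`.
#' @export
nb_kmeans <- function(normalized, timepoint_hr, K = 8, dispersion = 0.1,
                      seed = 1, max_iter = 100) {
  n <- nrow(normalized)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of genes")
  tps <- sort(unique(timepoint_hr))
  if (length(tps) < 2) stop("profiles need at least 2 timepoints")
  tpi <- match(timepoint_hr, tps)
  alpha <- if (length(dispersion) == 1) rep(dispersion, n) else
    dispersion[rownames(normalized)]
  y <- as.matrix(normalized)

  # per-timepoint mean profiles for initialization
  ybar <- sapply(tps, function(t) rowMeans(y[, timepoint_hr == t, drop = FALSE]))
  lz <- log2(ybar + 0.5)
  lz <- sweep(lz, 1, rowMeans(lz))
  sdv <- pmax(apply(lz, 1, stats::sd), 1e-8)
  lz <- sweep(lz, 1, sdv, `/`)

  # candidate-cluster log-likelihood for every gene given profile f (length
  # |tps|, mean 1): a_g = sum(y) / sum(f at samples), mu = a_g * f
  cand_ll <- function(f) {
    fj <- f[tpi]
    a <- pmax(rowSums(y) / sum(fj), 1e-8)
    nb_loglik_rows(y, a, fj, alpha)
  }
  profile_of <- function(members) {
    a <- pmax(rowSums(y[members, , drop = FALSE]) / ncol(y), 1e-8)
    rel <- sweep(y[members, , drop = FALSE], 1, a, `/`)
    f <- vapply(tps, function(t)
      mean(rel[, timepoint_hr == t, drop = FALSE]), numeric(1))
    f <- pmax(f, 1e-6)
    f / mean(f)
  }

  if (K == 1) {
    f <- matrix(profile_of(seq_len(n)), 1)
    colnames(f) <- paste0("t", tps)
    cl <- rep(1L, n); names(cl) <- rownames(y)
    return(structure(list(cluster = cl, profiles = f,
                          loglik = sum(cand_ll(f[1, ])), n_iterations = 0L,
                          K = 1L),
                     class = "cluster_assignment"))
  }

  with_seed(seed, {
    # k-means++ seeding on standardized log profiles
    centers <- integer(K)
    centers[1] <- sample.int(n, 1)
    d2 <- rowSums((lz - matrix(lz[centers[1], ], n, ncol(lz), byrow = TRUE))^2)
    for (k in 2:K) {
      pr <- d2 / sum(d2)
      centers[k] <- sample.int(n, 1, prob = pr)
      d2 <- pmin(d2, rowSums((lz - matrix(lz[centers[k], ], n, ncol(lz),
                                          byrow = TRUE))^2))
    }
    profiles <- t(vapply(centers, function(g) {
      f <- pmax(ybar[g, ] / mean(ybar[g, ]), 1e-6); f / mean(f)
    }, numeric(length(tps))))

    cl <- integer(n)
    ll_trace <- numeric(0)
    best_ll <- -Inf
    for (iter in seq_len(max_iter)) {
      llmat <- vapply(seq_len(K), function(k) cand_ll(profiles[k, ]),
                      numeric(n))
      new_cl <- max.col(llmat, ties.method = "first")
      # re-seed empty clusters from the worst-fit gene
      for (k in which(tabulate(new_cl, K) == 0)) {
        fit <- llmat[cbind(seq_len(n), new_cl)]
        worst <- which.min(fit)
        new_cl[worst] <- k
        profiles[k, ] <- profile_of(worst)
        message("nb_kmeans: re-seeded empty cluster ", k)
      }
      total <- sum(vapply(seq_len(K), function(k) cand_ll(profiles[k, ]),
                          numeric(n))[cbind(seq_len(n), new_cl)])
      if (total < best_ll - 1e-8) break      # likelihood would drop: stop
      ll_trace <- c(ll_trace, total)
      best_ll <- total
      stable <- identical(new_cl, cl)
      cl <- new_cl
      if (stable && iter > 1) break
      for (k in seq_len(K)) profiles[k, ] <- profile_of(which(cl == k))
    }
    colnames(profiles) <- paste0("t", tps)
    names(cl) <- rownames(y)
    structure(list(cluster = cl, profiles = profiles, loglik = ll_trace,
                   n_iterations = length(ll_trace), K = as.integer(K)),
              class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("NB model-based K-means:", x$K, "clusters,",
      length(x$cluster), "genes,", x$n_iterations, "iterations\n")
  print(table(cluster = x$cluster))
  invisible(x)
}
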