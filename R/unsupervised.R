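# Unsupervised analysis: hierarchical clustering with Pearson-correlation
# distance and Ward linkage, and consensus clustering by non-negative
# matrix factorization with multiplicative Kullback-Leibler (Brunet)
# updates over seeded random restarts.

#' Hierarchical clustering of patient profiles
#'
#' Agglomerative clustering of the rows of a patient x feature matrix
#' using distance `1 - Pearson correlation` between profiles and Ward
#' linkage (`ward.D2`), cut at K clusters.
#'
#' @param mat Patient x feature matrix (no missing values).
#' @param k Number of clusters.
#' @return Integer cluster labels named by patient.
#' @export
hierarchical_clusters <- function(mat, k) {
  if (k > nrow(mat)) stop_("k exceeds the number of patients")
  sds <- apply(mat, 1, sd)
  if (any(sds == 0))
    stop_("constant feature profile for patient(s): %s",
          paste(rownames(mat)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(t(mat)))
  cutree(hclust(d, method = "ward.D2"), k)
}

# Kullback-Leibler divergence D(V || WH), the Brunet objective
.kl_div <- function(V, WH) {
  eps <- 1e-12
  sum(V * log((V + eps) / (WH + eps)) - V + WH)
}

#' Non-negative matrix factorization with Brunet updates
#'
#' Factorizes a non-negative `features x samples` matrix V into W
#' (features x k) and H (k x samples) by multiplicative updates that
#' monotonically decrease the Kullback-Leibler divergence D(V || WH).
#' Random uniform initialization, seeded.
#'
#' @param V Non-negative matrix.
#' @param k Factorization rank, `k < min(dim(V))`.
#' @param n_iter Maximum update iterations (default 2000).
#' @param tol Relative divergence-change stopping tolerance, checked every
#'   10 iterations (default 1e-5).
#' @param seed Seed for the random initialization.
#' @return List `W`, `H`, `divergence` (trace at the 10-iteration
#'   checkpoints), `iterations`.
#' @export
nmf_factorize <- function(V, k, n_iter = 2000, tol = 1e-5, seed = NULL) {
  if (any(V < 0))
    stop_("V has negative entries; shift/scale features first (see nmf_preprocess)")
  if (k >= min(dim(V))) stop_("k must be below both matrix dimensions")
  n <- nrow(V); m <- ncol(V)
  eps <- .Machine$double.eps
  with_seed(seed, {
    W <- matrix(runif(n * k, 0, max(V)), n, k)
    H <- matrix(runif(k * m, 0, 1), k, m)
    trace <- numeric(0)
    last <- Inf
    it <- 0L
    while (it < n_iter) {
      it <- it + 1L
      WH <- W %*% H
      H <- H * (t(W) %*% (V / (WH + eps))) / (colSums(W) + eps)
      WH <- W %*% H
      W <- W * ((V / (WH + eps)) %*% t(H)) /
        matrix(rowSums(H), n, k, byrow = TRUE)
      if (it %% 10L == 0L) {
        d <- .kl_div(V, W %*% H)
        trace <- c(trace, d)
        if (is.finite(last) && abs(last - d) <= tol * max(abs(last), 1)) break
        last <- d
      }
    }
    list(W = W, H = H, divergence = trace, iterations = it)
  })
}

#' Shift-and-scale features for NMF
#'
#' NMF requires non-negative input while standardized spatial statistics
#' are signed; each feature (row) is shifted by its minimum and scaled to
#' \[0, 1\]. Constant features are dropped with a warning.
#'
#' @param V Features x samples matrix.
#' @return Non-negative matrix of the same orientation.
#' @export
nmf_preprocess <- function(V) {
  rng <- apply(V, 1, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    warning(sprintf("dropping %d constant feature(s) before NMF",
                    sum(span == 0)))
    V <- V[span > 0, , drop = FALSE]
    rng <- rng[, span > 0, drop = FALSE]
    span <- span[span > 0]
  }
  (V - rng[1, ]) / span
}

#' Consensus NMF clustering over a range of K
#'
#' For each K, `n_runs` seeded NMF restarts assign every sample to its
#' argmax-coefficient cluster; the consensus matrix holds the fraction of
#' runs co-clustering each sample pair. Final labels come from
#' average-linkage hierarchical clustering of `1 - consensus`; the
#' cophenetic correlation measures consensus stability.
#'
#' @param V Non-negative features x samples matrix (see
#'   [nmf_preprocess()]).
#' @param k_range Candidate cluster numbers (default 2..5).
#' @param n_runs Random restarts per K (default 20).
#' @param seed Base seed; run seeds are derived from it.
#' @param n_iter,tol Passed to [nmf_factorize()].
#' @return Named list (one element per K) of `ClusteringResult` lists:
#'   `k`, `labels`, `consensus`, `cophenetic`, `W`, `H` (best-divergence
#'   run), `top_features`.
#' @export
consensus_cluster <- function(V, k_range = 2:5, n_runs = 20, seed = 1,
                              n_iter = 2000, tol = 1e-5) {
  m <- ncol(V)
  samples <- colnames(V) %||% as.character(seq_len(m))
  out <- list()
  for (k in k_range) {
    if (k < 2) stop_("consensus clustering needs K >= 2")
    co <- matrix(0, m, m, dimnames = list(samples, samples))
    best <- NULL; best_div <- Inf
    for (run in seq_len(n_runs)) {
      fit <- nmf_factorize(V, k, n_iter = n_iter, tol = tol,
                           seed = derive_seed(seed, sprintf("k%d_run%d", k, run)))
      lab <- apply(fit$H, 2, which.max) # ties -> lowest index
      co <- co + outer(lab, lab, `==`)
      div <- .kl_div(V, fit$W %*% fit$H)
      if (div < best_div) { best_div <- div; best <- fit }
    }
    co <- co / n_runs
    hc <- hclust(as.dist(1 - co), method = "average")
    labels <- cutree(hc, k)
    dd <- as.dist(1 - co)
    coph <- if (sd(dd) == 0) 1.0 else suppressWarnings(
      cor(cophenetic(hc), dd))
    if (is.na(coph)) coph <- 1.0
    rownames(best$W) <- rownames(V)
    out[[as.character(k)]] <- list(
      method = "consensus_nmf", k = k, labels = labels, consensus = co,
      cophenetic = coph, W = best$W, H = best$H,
      top_features = top_contributing_features(best$W))
  }
  out
}

#' Top contributing features per NMF basis column
#'
#' Per cluster (basis column), the features whose basis weight is at least
#' `threshold` times the column maximum.
#'
#' @param W Non-negative basis matrix (features x K) with feature
#'   rownames.
#' @param threshold Relative contribution cut (default 0.8).
#' @return List of feature-name vectors, one per column.
#' @export
top_contributing_features <- function(W, threshold = 0.8) {
  if (any(W < 0)) stop_("W must be non-negative")
  rn <- rownames(W) %||% as.character(seq_len(nrow(W)))
  lapply(seq_len(ncol(W)), function(j) {
    mx <- max(W[, j])
    if (mx == 0) {
      warning(sprintf("basis column %d is all zero", j))
      return(character(0))
    }
    rn[W[, j] >= threshold * mx]
  })
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Cluster label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
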