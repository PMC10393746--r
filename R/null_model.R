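# Monte-Carlo calibration of the radius-based statistics under complete
# spatial randomness (CSR) matched to a region's window and observed
# counts. The study this package implements defers the standardization
# sigma to closed-form results that it does not reproduce; here the null
# mean and sigma are estimated by seeded simulation of a binomial process
# (fixed counts, uniform positions in the same window), which also absorbs
# the edge-effect bias of the uncorrected raw estimators.

#' Null-model configuration for feature extraction
#'
#' @param n_null Number of CSR replicates per null model (default 199).
#' @param grid_dim F-function grid `c(nx, ny)` (default 100 x 100).
#' @param seed Base seed; per-null seeds are derived deterministically from
#'   it, so identical configs give identical features.
#' @param center `"theoretical"` standardizes against the closed-form CSR
#'   expectation (as the defining formulas are printed); `"null"` against
#'   the Monte-Carlo null mean, which removes edge-effect bias.
#' @param mad_constant MAD multiplier (default 1, no consistency constant).
#' @param cache Optional environment to reuse null models across regions
#'   sharing a window; keys include window dimensions and counts.
#' @return A list of class `null_config`.
#' @export
null_config <- function(n_null = 199, grid_dim = c(100, 100), seed = 1,
                        center = c("theoretical", "null"),
                        mad_constant = 1, cache = NULL) {
  structure(list(n_null = as.integer(n_null), grid_dim = as.integer(grid_dim),
                 seed = seed, center = match.arg(center),
                 mad_constant = mad_constant, cache = cache),
            class = "null_config")
}

# simulate n uniform points in a window
.runif_window <- function(n, window) {
  list(x = runif(n, window$xmin, window$xmax),
       y = runif(n, window$ymin, window$ymax))
}

.null_summarize <- function(sims, n_null) {
  # sims: n_null x n_radii matrix, possibly with NA rows
  ok <- rowSums(is.na(sims)) == 0
  defined <- sum(ok)
  if (defined < 2) {
    nr <- ncol(sims)
    return(list(mean = rep(NA_real_, nr), sigma = rep(NA_real_, nr),
                n_defined = defined, unreliable = TRUE))
  }
  list(mean = colMeans(sims[ok, , drop = FALSE]),
       sigma = apply(sims[ok, , drop = FALSE], 2, sd),
       n_defined = defined,
       unreliable = defined <= n_null / 2)
}

# Null models for G, K and L of an (N_i, N_j) pair in one pass: positions
# are simulated once per replicate and all three statistics evaluated on
# them. self = TRUE simulates a single set of N_i points (i = j case).
null_pair_models <- function(window, n_i, n_j, radii, n_null = 199,
                             seed = NULL, self = FALSE) {
  nr <- length(radii)
  gs <- matrix(NA_real_, n_null, nr)
  ks <- matrix(NA_real_, n_null, nr)
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      pi_ <- .runif_window(n_i, window)
      if (self) {
        pj <- pi_
        idi <- seq_len(n_i); idj <- idi
      } else {
        pj <- .runif_window(n_j, window)
        idi <- seq_len(n_i); idj <- n_i + seq_len(n_j)
      }
      eligible <- if (self) n_i >= 2 else n_j >= 1
      if (n_i >= 1 && eligible)
        gs[b, ] <- .raw_G(pi_$x, pi_$y, idi, pj$x, pj$y, idj, radii)
      if (n_i >= 1 && n_j >= 1)
        ks[b, ] <- .raw_K(window$area, pi_$x, pi_$y, idi, pj$x, pj$y, idj,
                          radii)
    }
  })
  list(G = c(list(statistic = "G", radii = radii),
             .null_summarize(gs, n_null)),
       K = c(list(statistic = "K", radii = radii),
             .null_summarize(ks, n_null)),
       L = c(list(statistic = "L", radii = radii),
             .null_summarize(sqrt(ks / pi), n_null)))
}

# Null model for the F function of N_i points.
null_F_model <- function(window, n_i, radii, n_null = 199, seed = NULL,
                         grid_dim = c(100, 100)) {
  fs <- matrix(NA_real_, n_null, length(radii))
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      p <- .runif_window(n_i, window)
      if (n_i >= 1) fs[b, ] <- .raw_F(window, p$x, p$y, radii, grid_dim)
    }
  })
  c(list(statistic = "F", radii = radii), .null_summarize(fs, n_null))
}

#' Monte-Carlo null mean and sigma of a raw statistic under CSR
#'
#' Simulates `n_null` independent uniform placements of the observed
#' counts in the window, evaluates the raw statistic on each, and returns
#' the sample mean and standard deviation per radius. Deterministic given
#' `seed`.
#'
#' @param window A [tme_window()].
#' @param n_i,n_j Fixed counts of the two types (`n_j` ignored for F;
#'   `n_j = n_i` with `self = TRUE` for the i = j case).
#' @param statistic One of `"F"`, `"G"`, `"K"`, `"L"`.
#' @param r Radius or vector of radii (um).
#' @param n_null Number of replicates (>= 2), default 199.
#' @param seed Seed for reproducibility.
#' @param grid_dim F-function grid.
#' @param self Simulate a single point set (i = j)?
#' @return List with `statistic`, `radii`, `mean`, `sigma`, `n_defined`
#'   and an `unreliable` flag (statistic undefined in more than half of
#'   the replicates).
#' @export
null_sigma_mc <- function(window, n_i, n_j = NULL,
                          statistic = c("F", "G", "K", "L"), r,
                          n_null = 199, seed = NULL,
                          grid_dim = c(100, 100), self = FALSE) {
  statistic <- match.arg(statistic)
  if (n_null < 2) stop_("n_null must be >= 2")
  if (statistic == "F")
    return(null_F_model(window, n_i, r, n_null, seed, grid_dim))
  if (is.null(n_j)) {
    if (!self) stop_("n_j required for pair statistics")
    n_j <- n_i
  }
  null_pair_models(window, n_i, n_j, r, n_null, seed, self)[[statistic]]
}
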