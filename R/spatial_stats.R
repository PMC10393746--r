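# Per-region statistics on marked point patterns: non-spatial, local,
# radius-based (raw + theoretical baselines) and global. All estimators are
# the plain empirical means of their defining formulas; no edge correction
# is applied (edge effects are absorbed by the matched-window Monte-Carlo
# null used for standardization, see null_model.R). Statistics whose
# preconditions fail (insufficient counts) return NA, never an error, so
# region-level extraction always completes.

# ---- non-spatial ----------------------------------------------------------

#' Normalized count of a cell type
#'
#' Count of cells carrying the type mark divided by the total number of
#' cells in the region (including unmarked "other" cells).
#'
#' @param pattern A `region_pattern`.
#' @param type Analysis cell-type name.
#' @return Fraction in \[0, 1\], or `NA` for an empty region.
#' @export
normalized_count <- function(pattern, type) {
  if (pattern$n_total == 0L) return(NA_real_)
  unname(pattern$n_by_type[[type]] / pattern$n_total)
}

#' Cell density of a type
#'
#' Count divided by the window area; the intensity lambda_i in cells/um^2.
#'
#' @inheritParams normalized_count
#' @return Intensity (per um^2).
#' @export
cell_density <- function(pattern, type) {
  unname(pattern$n_by_type[[type]] / pattern$window$area)
}

# ---- local ----------------------------------------------------------------

#' Nearest-neighbour distance set between two cell types
#'
#' For each type-i cell, the Euclidean distance to the nearest type-j cell.
#' The cell itself never counts as its own neighbour, so for i = j (or
#' overlapping hierarchy marks) distances are to the nearest *other* cell.
#'
#' @param pattern A `region_pattern`.
#' @param type_i,type_j Analysis cell-type names; `type_j = "*"` means all
#'   cells not carrying mark `type_i`.
#' @return Numeric vector of length N_i, or `NULL` when counts are
#'   insufficient (N_i = 0, or no eligible neighbour).
#' @export
nearest_distance_set <- function(pattern, type_i, type_j) {
  ci <- type_coords(pattern, type_i)
  cj <- type_coords(pattern, type_j, exclude = type_i)
  if (length(ci$x) == 0L || length(cj$x) == 0L) return(NULL)
  if (length(cj$x) == 1L && length(ci$x) == 1L && ci$id[1] == cj$id[1])
    return(NULL) # single cell carrying both marks: no neighbour exists
  d <- cpp_nn_dist(ci$x, ci$y, ci$id, cj$x, cj$y, cj$id)
  if (any(!is.finite(d))) return(NULL)
  d
}

#' Median minimal distance and its median absolute deviation
#'
#' MMD_ij is the median of the nearest-neighbour distances from type-i
#' cells to type-j cells; MADMD_ij the raw median absolute deviation of
#' the same set (no consistency constant by default).
#'
#' @inheritParams nearest_distance_set
#' @param mad_constant Multiplier for the MAD (default 1; use 1.4826 for
#'   the normal-consistent convention).
#' @return Named numeric `c(mmd, madmd)`; both `NA` when undefined.
#' @export
local_distance_stats <- function(pattern, type_i, type_j, mad_constant = 1) {
  d <- nearest_distance_set(pattern, type_i, type_j)
  if (is.null(d)) return(c(mmd = NA_real_, madmd = NA_real_))
  c(mmd = median(d), madmd = mad_raw(d, mad_constant))
}

#' Median spatial score and its median absolute deviation
#'
#' Per tumor cell: the distance to the nearest T cell divided by the
#' distance from that T cell to its nearest macrophage. Tumor cells whose
#' nearest T cell coincides with a macrophage (zero denominator) are
#' excluded from the median; if every score is excluded, or any of the
#' three lineages is absent, the statistics are missing.
#'
#' @param pattern A `region_pattern`.
#' @param mad_constant See [local_distance_stats()].
#' @return Named numeric `c(mss, madss)`.
#' @export
spatial_score_stats <- function(pattern, mad_constant = 1) {
  miss <- c(mss = NA_real_, madss = NA_real_)
  tu <- type_coords(pattern, "Tumor")
  tc <- type_coords(pattern, "Tcell")
  mp <- type_coords(pattern, "Macrophage")
  if (!length(tu$x) || !length(tc$x) || !length(mp$x)) return(miss)
  # nearest T cell per tumor cell (index of the argmin, recomputed in R to
  # recover WHICH T cell; counts are small for the three lineage sets)
  nt <- vapply(seq_along(tu$x), function(a) {
    d2 <- (tu$x[a] - tc$x)^2 + (tu$y[a] - tc$y)^2
    which.min(d2)
  }, integer(1))
  d_tumor_t <- sqrt((tu$x - tc$x[nt])^2 + (tu$y - tc$y[nt])^2)
  d_t_mac <- cpp_nn_dist(tc$x, tc$y, tc$id, mp$x, mp$y, mp$id)
  denom <- d_t_mac[nt]
  keep <- denom > 0
  if (!any(keep)) return(miss)
  s <- d_tumor_t[keep] / denom[keep]
  c(mss = median(s), madss = mad_raw(s, mad_constant))
}

# ---- radius-based raw estimators -----------------------------------------

# raw kernels on bare coordinates (shared with the Monte-Carlo null)
.raw_F <- function(window, x, y, radii, grid_dim) {
  d <- cpp_grid_nn_dist(window$xmin, window$xmax, window$ymin, window$ymax,
                        grid_dim[1], grid_dim[2], x, y)
  vapply(radii, function(r) mean(d <= r), numeric(1))
}

.raw_G <- function(xi, yi, idi, xj, yj, idj, radii) {
  d <- cpp_nn_dist(xi, yi, idi, xj, yj, idj)
  vapply(radii, function(r) mean(d <= r), numeric(1))
}

.raw_K <- function(area, xi, yi, idi, xj, yj, idj, radii) {
  lambda_j <- length(xj) / area
  counts <- cpp_count_within(xi, yi, idi, xj, yj, idj, radii)
  (counts / length(xi)) / lambda_j
}

#' Empty-space function F (raw)
#'
#' Fraction of evenly spaced grid points whose distance to the nearest
#' type-i cell is at most r. The grid is the set of cell centres of an
#' `nx x ny` partition of the window (default 100 x 100).
#'
#' @param pattern A `region_pattern`.
#' @param type_i Analysis cell-type name.
#' @param r Radius or vector of radii (um).
#' @param grid_dim Integer 2-vector `c(nx, ny)`.
#' @return Numeric vector of fractions, `NA` when N_i = 0.
#' @export
empty_space_F <- function(pattern, type_i, r, grid_dim = c(100, 100)) {
  ci <- type_coords(pattern, type_i)
  if (length(ci$x) == 0L) return(rep(NA_real_, length(r)))
  .raw_F(pattern$window, ci$x, ci$y, r, grid_dim)
}

#' Nearest-neighbour function G (raw)
#'
#' Fraction of type-i cells whose nearest type-j cell lies within r. For
#' i = j the cell itself is excluded (strictly positive distances).
#'
#' @inheritParams nearest_distance_set
#' @param r Radius or vector of radii (um).
#' @return Numeric vector of fractions, `NA` when counts are insufficient.
#' @export
nearest_neighbor_G <- function(pattern, type_i, type_j, r) {
  d <- nearest_distance_set(pattern, type_i, type_j)
  if (is.null(d)) return(rep(NA_real_, length(r)))
  vapply(r, function(rr) mean(d <= rr), numeric(1))
}

#' Ripley's K function (raw)
#'
#' Mean number of type-j cells at distance strictly less than r from a
#' type-i cell, normalized by the type-j intensity. For i = j the cell
#' itself is excluded from the neighbourhood count.
#'
#' @inheritParams nearest_neighbor_G
#' @return Numeric vector (um^2); `NA` when N_i = 0 or lambda_j = 0.
#' @export
ripley_K <- function(pattern, type_i, type_j, r) {
  ci <- type_coords(pattern, type_i)
  cj <- type_coords(pattern, type_j, exclude = type_i)
  if (length(ci$x) == 0L || length(cj$x) == 0L)
    return(rep(NA_real_, length(r)))
  .raw_K(pattern$window$area, ci$x, ci$y, ci$id, cj$x, cj$y, cj$id, r)
}

#' Ripley's L function (raw)
#'
#' Variance-stabilized K: `L = sqrt(K / pi)`, with CSR expectation r.
#'
#' @inheritParams ripley_K
#' @return Numeric vector (um); `NA` where K is missing.
#' @export
ripley_L <- function(pattern, type_i, type_j, r) {
  sqrt(ripley_K(pattern, type_i, type_j, r) / pi)
}

# ---- theoretical baselines ------------------------------------------------

#' Theoretical CSR baseline of a radius-based statistic
#'
#' Closed-form expectations under homogeneous Poisson cells:
#' `F_theo = 1 - exp(-lambda * pi * r^2)` (lambda = intensity of type i),
#' `G_theo = 1 - exp(-lambda_j * pi * r^2)`, `K_theo = pi * r^2`,
#' `L_theo = r`.
#'
#' @param statistic One of `"F"`, `"G"`, `"K"`, `"L"`.
#' @param lambda Intensity (per um^2); required for F and G, ignored for
#'   K and L.
#' @param r Radius or vector of radii (um).
#' @return Numeric vector of baseline values.
#' @export
theoretical_baseline <- function(statistic, lambda = NULL, r) {
  statistic <- match.arg(statistic, c("F", "G", "K", "L"))
  if (statistic %in% c("F", "G")) {
    if (is.null(lambda) || any(lambda < 0))
      stop_("F/G baselines need a non-negative intensity lambda")
    1 - exp(-lambda * pi * r^2)
  } else if (statistic == "K") {
    pi * r^2
  } else {
    r
  }
}

#' Standardize a raw statistic against its baseline
#'
#' `z = (raw - baseline) / sigma`. Missing inputs or non-positive sigma
#' propagate as `NA`.
#'
#' @param raw Raw statistic value(s).
#' @param baseline Baseline value(s) (theoretical or null mean).
#' @param sigma Null standard deviation(s).
#' @return Standardized value(s), dimensionless.
#' @export
standardize_statistic <- function(raw, baseline, sigma) {
  z <- (raw - baseline) / sigma
  z[!is.na(sigma) & sigma <= 0] <- NA_real_
  z
}

# ---- global ---------------------------------------------------------------

#' Chi-squared inhomogeneity statistic
#'
#' The window is divided into a 5 x 5 grid of equal rectangles; the
#' statistic is `sum_R (lambda_i(R) - lambda_i)^2 / lambda_i` over the 25
#' rectangle densities. Zero iff the type is perfectly evenly spread.
#'
#' @inheritParams normalized_count
#' @param nx,ny Grid subdivision (default 5 x 5 per the defining formula).
#' @return Statistic (per um^2); `NA` when the type has no cells.
#' @export
chi_squared_inhomogeneity <- function(pattern, type, nx = 5, ny = 5) {
  ci <- type_coords(pattern, type)
  n <- length(ci$x)
  if (n == 0L) return(NA_real_)
  w <- pattern$window
  lambda <- n / w$area
  # bin cells; right/top boundary cells fall in the last rectangle
  ix <- pmin(pmax(ceiling((ci$x - w$xmin) / (w$xmax - w$xmin) * nx), 1), nx)
  iy <- pmin(pmax(ceiling((ci$y - w$ymin) / (w$ymax - w$ymin) * ny), 1), ny)
  counts <- tabulate(ix + (iy - 1L) * nx, nbins = nx * ny)
  area_r <- w$area / (nx * ny)
  sum((counts / area_r - lambda)^2) / lambda
}

#' Median distance and MAD over all cross-pairs
#'
#' MD_ij is the median over all N_i x N_j pairwise distances between the
#' two types (same-cell pairs, the zero diagonal for i = j, excluded);
#' MADD_ij the raw median absolute deviation of the same set.
#'
#' @inheritParams local_distance_stats
#' @return Named numeric `c(md, madd)`; `NA` when counts are insufficient.
#' @export
global_distance_stats <- function(pattern, type_i, type_j, mad_constant = 1) {
  ci <- type_coords(pattern, type_i)
  cj <- type_coords(pattern, type_j, exclude = NULL)
  if (identical(type_i, type_j)) cj <- ci
  miss <- c(md = NA_real_, madd = NA_real_)
  if (length(ci$x) == 0L || length(cj$x) == 0L) return(miss)
  d <- cpp_pairwise_dists(ci$x, ci$y, ci$id, cj$x, cj$y, cj$id)
  if (length(d) == 0L) return(miss)
  c(md = median(d), madd = mad_raw(d, mad_constant))
}
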