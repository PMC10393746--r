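# Builders for tiny hand-placed patterns and pure-R brute-force oracles.

# one cell record row
cell_row <- function(x, y, phenotype, region_id = "r1",
                     region_class = "tumor", patient_id = "p1") {
  data.frame(x = x, y = y, phenotype = phenotype, region_id = region_id,
             region_class = region_class, patient_id = patient_id,
             stringsAsFactors = FALSE)
}

# pattern from coordinate vectors and phenotypes, lineage hierarchy
toy_pattern <- function(x, y, phenotype, window = NULL,
                        hierarchy = lineage_hierarchy(), ...) {
  cells <- cell_row(x, y, phenotype, ...)
  build_hierarchy_marks(cells, hierarchy, window)
}

# phenotype representatives for the three lineages
PH_TUMOR <- "PAX5+PD-L1-"
PH_TCELL <- "CD3+CD8-PD-1-"
PH_MAC <- "CD163+PD-L1-"

# ---- independent O(n^2) pure-R oracles ------------------------------------

oracle_nn_dist <- function(xi, yi, xj, yj, idi, idj) {
  vapply(seq_along(xi), function(a) {
    d <- sqrt((xi[a] - xj)^2 + (yi[a] - yj)^2)
    d[idj == idi[a]] <- Inf
    min(d)
  }, numeric(1))
}

oracle_G <- function(xi, yi, xj, yj, idi, idj, r) {
  d <- oracle_nn_dist(xi, yi, xj, yj, idi, idj)
  vapply(r, function(rr) mean(d <= rr), numeric(1))
}

oracle_K <- function(area, xi, yi, xj, yj, idi, idj, r) {
  lambda_j <- length(xj) / area
  vapply(r, function(rr) {
    tot <- 0
    for (a in seq_along(xi)) {
      d <- sqrt((xi[a] - xj)^2 + (yi[a] - yj)^2)
      tot <- tot + sum(d < rr & idj != idi[a])
    }
    (tot / length(xi)) / lambda_j
  }, numeric(1))
}

oracle_F <- function(window, xp, yp, r, grid_dim) {
  gx <- window$xmin + (seq_len(grid_dim[1]) - 0.5) *
    (window$xmax - window$xmin) / grid_dim[1]
  gy <- window$ymin + (seq_len(grid_dim[2]) - 0.5) *
    (window$ymax - window$ymin) / grid_dim[2]
  g <- expand.grid(x = gx, y = gy)
  d <- vapply(seq_len(nrow(g)), function(a)
    min(sqrt((g$x[a] - xp)^2 + (g$y[a] - yp)^2)), numeric(1))
  vapply(r, function(rr) mean(d <= rr), numeric(1))
}

oracle_pair_dists <- function(xi, yi, xj, yj, idi, idj) {
  out <- numeric(0)
  for (a in seq_along(xi)) {
    d <- sqrt((xi[a] - xj)^2 + (yi[a] - yj)^2)
    out <- c(out, d[idj != idi[a]])
  }
  out
}

# random CSR pattern of the three lineages with fixed counts
random_pattern <- function(n_tumor, n_tcell, n_mac, window, seed) {
  simulate_csr(
    setNames(c(1, 1, 1), c(PH_TUMOR, PH_TCELL, PH_MAC)), window,
    counts = setNames(c(n_tumor, n_tcell, n_mac),
                      c(PH_TUMOR, PH_TCELL, PH_MAC)),
    seed = seed, hierarchy = lineage_hierarchy())
}
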