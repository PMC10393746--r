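# Worked examples fixed by hand computation, plus structural invariants.

test_that("normalized counts and densities follow their definitions", {
  w <- tme_window(0, 100, 0, 100)
  p <- toy_pattern(x = 1:10, y = rep(1, 10),
                   phenotype = rep(c(PH_TUMOR, "other"), c(3, 7)),
                   window = w)
  expect_equal(normalized_count(p, "Tumor"), 0.3)
  expect_equal(normalized_count(p, "Tcell"), 0)
  expect_equal(cell_density(p, "Tumor"), 3e-4)
  p_all <- toy_pattern(1:10, rep(1, 10), rep(PH_TUMOR, 10), w)
  expect_equal(normalized_count(p_all, "Tumor"), 1)
  # doubling window side quarters the density
  p_big <- toy_pattern(1:10, rep(1, 10), rep(PH_TUMOR, 10),
                       tme_window(0, 200, 0, 200))
  expect_equal(cell_density(p_big, "Tumor"), cell_density(p_all, "Tumor") / 4)
})

test_that("nearest-distance sets match hand Euclidean computations", {
  w <- tme_window(-1, 60, -1, 60)
  p <- toy_pattern(c(0, 10, 0), c(0, 0, 5),
                   c(PH_TUMOR, PH_TUMOR, PH_TCELL), w)
  expect_equal(nearest_distance_set(p, "Tumor", "Tcell"),
               c(5, sqrt(125)), tolerance = 1e-12)
  st <- local_distance_stats(p, "Tumor", "Tcell")
  expect_equal(st[["mmd"]], 8.09017, tolerance = 1e-6)
  expect_equal(st[["madmd"]], 3.09017, tolerance = 1e-6)

  # i = j: nearest OTHER cell, symmetric distances
  p2 <- toy_pattern(c(0, 3), c(0, 4), rep(PH_TUMOR, 2), w)
  expect_equal(nearest_distance_set(p2, "Tumor", "Tumor"), c(5, 5))
  # coincident cells of different types: zero distance is legitimate
  p3 <- toy_pattern(c(2, 2), c(2, 2), c(PH_TUMOR, PH_TCELL), w)
  expect_equal(nearest_distance_set(p3, "Tumor", "Tcell"), 0)
  # insufficient counts propagate as missing, not errors
  expect_null(nearest_distance_set(p2, "Tumor", "Tcell"))
  st_na <- local_distance_stats(p2, "Tumor", "Tcell")
  expect_true(all(is.na(st_na)))
  expect_equal(local_distance_stats(p3, "Tumor", "Tcell")[["madmd"]], 0)
})

test_that("spatial score follows the tumor -> T cell -> macrophage chain", {
  w <- tme_window(-1, 10, -1, 10)
  # tumor (0,0); T cell (3,4) at 5; that T cell's macrophage (3,0) at 4
  p <- toy_pattern(c(0, 3, 3), c(0, 4, 0),
                   c(PH_TUMOR, PH_TCELL, PH_MAC), w)
  expect_equal(spatial_score_stats(p)[["mss"]], 1.25)
  # collinear at distances 2 and 2 -> score 1
  p2 <- toy_pattern(c(0, 2, 4), c(0, 0, 0),
                    c(PH_TUMOR, PH_TCELL, PH_MAC), w)
  expect_equal(spatial_score_stats(p2)[["mss"]], 1)
  # median of two tumor scores
  p3 <- toy_pattern(c(0, 8, 4, 6), c(0, 0, 0, 0),
                    c(PH_TUMOR, PH_TUMOR, PH_TCELL, PH_MAC), w)
  s <- spatial_score_stats(p3)
  expect_equal(s[["mss"]], median(c(4 / 2, 4 / 2)))
  # a missing lineage -> missing, not error
  p4 <- toy_pattern(c(0, 3), c(0, 4), c(PH_TUMOR, PH_TCELL), w)
  expect_true(all(is.na(spatial_score_stats(p4))))
  # T cell coincident with macrophage: that tumor cell is excluded
  p5 <- toy_pattern(c(0, 3, 3), c(0, 4, 4),
                    c(PH_TUMOR, PH_TCELL, PH_MAC), w)
  expect_true(all(is.na(spatial_score_stats(p5))))
})

test_that("F function matches hand grid distances", {
  p <- toy_pattern(5, 5, PH_TUMOR, tme_window(0, 10, 0, 10))
  # 2x2 grid: points (2.5,2.5)... each at sqrt(12.5) = 3.53553 from (5,5)
  expect_equal(empty_space_F(p, "Tumor", 5, grid_dim = c(2, 2)), 1)
  expect_equal(empty_space_F(p, "Tumor", 3, grid_dim = c(2, 2)), 0)
  expect_equal(empty_space_F(p, "Tumor", 0, grid_dim = c(2, 2)), 0)
  expect_true(is.na(empty_space_F(p, "Tcell", 5)))
})

test_that("G function matches hand nearest-neighbour fractions", {
  w <- tme_window(0, 100, 0, 100)
  p <- toy_pattern(c(0, 20, 0, 50), c(0, 0, 3, 50),
                   c(PH_TUMOR, PH_TUMOR, PH_TCELL, PH_TCELL), w)
  expect_equal(nearest_neighbor_G(p, "Tumor", "Tcell", 5), 0.5)
  expect_equal(nearest_neighbor_G(p, "Tumor", "Tcell", 150), 1)
  p2 <- toy_pattern(c(0, 7), c(0, 0), rep(PH_TUMOR, 2), w)
  expect_equal(nearest_neighbor_G(p2, "Tumor", "Tumor", 5), 0)
})

test_that("K and L match hand counts and the sqrt identity", {
  w <- tme_window(0, 100, 0, 100)
  p <- toy_pattern(c(0, 3, 30), c(0, 0, 0),
                   c(PH_TUMOR, PH_TCELL, PH_TCELL), w)
  expect_equal(ripley_K(p, "Tumor", "Tcell", 5), 5000)
  expect_equal(ripley_K(p, "Tumor", "Tcell", 50), 10000)
  expect_equal(ripley_L(p, "Tumor", "Tcell", 5), sqrt(5000 / pi))
  expect_equal(sqrt(5000 / pi), 39.89423, tolerance = 1e-6)
  # single i cell, i = j: self excluded -> K = 0 -> L = 0
  p1 <- toy_pattern(c(50, 10), c(50, 10), c(PH_TUMOR, PH_TCELL), w)
  expect_equal(ripley_K(p1, "Tumor", "Tumor", 10), 0)
  expect_equal(ripley_L(p1, "Tumor", "Tumor", 10), 0)
})

test_that("theoretical baselines evaluate the closed forms", {
  expect_equal(theoretical_baseline("K", r = 10), 100 * pi)
  expect_equal(theoretical_baseline("K", r = 10), 314.15927, tolerance = 1e-7)
  expect_equal(theoretical_baseline("L", r = 10), 10)
  expect_equal(theoretical_baseline("F", 0.001, 10), 1 - exp(-0.001 * pi * 100))
  expect_equal(theoretical_baseline("G", 0.001, 10),
               theoretical_baseline("F", 0.001, 10))
  expect_error(theoretical_baseline("F", -1, 10), "non-negative")
})

test_that("standardization is missing-aware arithmetic", {
  expect_equal(standardize_statistic(0.5, 0.3, 0.1), 2)
  expect_equal(standardize_statistic(0.3, 0.3, 0.1), 0)
  expect_equal(standardize_statistic(300, theoretical_baseline("K", r = 10), 50),
               -0.28319, tolerance = 1e-4)
  expect_true(is.na(standardize_statistic(1, 0.5, 0)))
  expect_true(is.na(standardize_statistic(1, 0.5, NA)))
})

test_that("chi-squared inhomogeneity matches the hand example", {
  w <- tme_window(0, 50, 0, 50)
  # 25 cells, one per 10x10 rectangle (at rectangle centres) -> 0
  g <- expand.grid(x = seq(5, 45, 10), y = seq(5, 45, 10))
  p_h <- toy_pattern(g$x, g$y, rep(PH_TUMOR, 25), w)
  expect_equal(chi_squared_inhomogeneity(p_h, "Tumor"), 0)
  # all 25 inside one rectangle -> 6.0
  set.seed(42)
  p_c <- toy_pattern(runif(25, 0, 10), runif(25, 0, 10),
                     rep(PH_TUMOR, 25), w)
  expect_equal(chi_squared_inhomogeneity(p_c, "Tumor"), 6)
  # translation invariance of cells + window jointly
  p_t <- toy_pattern(g$x + 100, g$y - 30, rep(PH_TUMOR, 25),
                     tme_window(100, 150, -30, 20))
  expect_equal(chi_squared_inhomogeneity(p_t, "Tumor"), 0)
  expect_true(is.na(chi_squared_inhomogeneity(p_h, "Tcell")))
})

test_that("global distance statistics exclude the diagonal", {
  w <- tme_window(-1, 10, -1, 10)
  p <- toy_pattern(c(0, 3, 0), c(0, 0, 4),
                   c(PH_TUMOR, PH_TCELL, PH_TCELL), w)
  g <- global_distance_stats(p, "Tumor", "Tcell")
  expect_equal(g[["md"]], 3.5)
  expect_equal(g[["madd"]], 0.5)
  p2 <- toy_pattern(c(0, 6), c(0, 0), rep(PH_TUMOR, 2), w)
  g2 <- global_distance_stats(p2, "Tumor", "Tumor")
  expect_equal(g2[["md"]], 6)
  expect_equal(g2[["madd"]], 0)
  expect_true(all(is.na(global_distance_stats(p2, "Tumor", "Tcell"))))
})

test_that("F/G/K/L are non-decreasing in r and L = sqrt(K/pi) exactly", {
  w <- tme_window(0, 300, 0, 300)
  radii <- c(2, 5, 10, 25, 50, 100)
  for (seed in 1:5) {
    p <- random_pattern(40, 30, 20, w, seed)
    for (pair in list(c("Tumor", "Tcell"), c("Tcell", "Tcell"),
                      c("Macrophage", "*"))) {
      g <- nearest_neighbor_G(p, pair[1], pair[2], radii)
      k <- ripley_K(p, pair[1], pair[2], radii)
      l <- ripley_L(p, pair[1], pair[2], radii)
      expect_true(all(diff(g) >= 0))
      expect_true(all(diff(k) >= 0))
      expect_identical(l, sqrt(k / pi))
    }
    f <- empty_space_F(p, "Tumor", radii, grid_dim = c(20, 20))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("statistics are invariant under rigid motions and scale correctly", {
  w <- tme_window(0, 200, 0, 200)
  p <- random_pattern(30, 25, 15, w, seed = 7)
  radii <- c(5, 20, 60)

  # joint translation
  tr <- p
  tr$x <- p$x + 57.3; tr$y <- p$y - 12.9
  tr$window <- tme_window(w$xmin + 57.3, w$xmax + 57.3,
                          w$ymin - 12.9, w$ymax - 12.9)
  # 90-degree rotation about the window centre (square window)
  rot <- p
  rot$x <- 200 - p$y; rot$y <- p$x
  for (q in list(tr, rot)) {
    expect_equal(ripley_K(q, "Tumor", "Tcell", radii),
                 ripley_K(p, "Tumor", "Tcell", radii), tolerance = 1e-9)
    expect_equal(nearest_neighbor_G(q, "Tcell", "Macrophage", radii),
                 nearest_neighbor_G(p, "Tcell", "Macrophage", radii),
                 tolerance = 1e-9)
    expect_equal(local_distance_stats(q, "Tumor", "Tcell"),
                 local_distance_stats(p, "Tumor", "Tcell"),
                 tolerance = 1e-9)
    expect_equal(global_distance_stats(q, "Tumor", "Tcell"),
                 global_distance_stats(p, "Tumor", "Tcell"),
                 tolerance = 1e-9)
    expect_equal(chi_squared_inhomogeneity(q, "Tumor"),
                 chi_squared_inhomogeneity(p, "Tumor"), tolerance = 1e-9)
  }

  # scaling by c: distances scale by c, lambda by 1/c^2, K(c., c r) = c^2 K(., r)
  cs <- 2.5
  sc <- p
  sc$x <- p$x * cs; sc$y <- p$y * cs
  sc$window <- tme_window(0, 200 * cs, 0, 200 * cs)
  expect_equal(local_distance_stats(sc, "Tumor", "Tcell"),
               cs * local_distance_stats(p, "Tumor", "Tcell"),
               tolerance = 1e-9)
  expect_equal(global_distance_stats(sc, "Tumor", "Tcell"),
               cs * global_distance_stats(p, "Tumor", "Tcell"),
               tolerance = 1e-9)
  expect_equal(cell_density(sc, "Tumor"), cell_density(p, "Tumor") / cs^2,
               tolerance = 1e-12)
  expect_equal(ripley_K(sc, "Tumor", "Tcell", cs * radii),
               cs^2 * ripley_K(p, "Tumor", "Tcell", radii),
               tolerance = 1e-9)
})
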