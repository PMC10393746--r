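test_that("CSR simulator hits its intensity and respects seed/window", {
  w <- tme_window(0, 1000, 0, 1000)
  lam <- c("PAX5+PD-L1-" = 1e-3)
  # mean count over seeds within 3 SE of lambda * area = 1000
  counts <- vapply(1:120, function(s)
    simulate_csr(lam, w, seed = s)$n_total, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1000), 3 * se)
  expect_equal(simulate_csr(c("other" = 0), w, seed = 1)$n_total, 0)
  a <- simulate_csr(lam, w, seed = 33)
  b <- simulate_csr(lam, w, seed = 33)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_true(all(a$x >= 0 & a$x <= 1000 & a$y >= 0 & a$y <= 1000))
  expect_error(simulate_csr(c("other" = -1), w), ">= 0")
})

test_that("Thomas clusters are detected by standardized K and vanish as sigma grows", {
  w <- tme_window(0, 600, 0, 600)
  h <- lineage_hierarchy()
  # sigma 10 um clusters: z(K_ii) at r = 25 positive in >= 90% of seeds
  hits <- 0; n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    p <- simulate_clustered(PH_MAC, parent_intensity = 2e-5,
                            mean_offspring = 10, sigma = 10, w,
                            seed = 100 + s, hierarchy = h)
    n <- p$n_by_type[["Macrophage"]]
    if (n < 2) next
    nm <- null_sigma_mc(w, n, statistic = "K", r = 25, n_null = 39,
                        seed = 5, self = TRUE)
    z <- (ripley_K(p, "Macrophage", "Macrophage", 25) - nm$mean) / nm$sigma
    if (!is.na(z) && z > 0) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
  # parent intensity 0 -> empty
  expect_equal(simulate_clustered(PH_MAC, 0, 10, 10, w, seed = 1,
                                  hierarchy = h)$n_total, 0)
  # huge sigma approaches CSR: mean z over seeds within 3 SE of 0
  zs <- vapply(1:40, function(s) {
    p <- simulate_clustered(PH_MAC, 2e-5, 10, sigma = 500, w,
                            seed = 200 + s, hierarchy = h)
    n <- p$n_by_type[["Macrophage"]]
    if (n < 2) return(NA_real_)
    nm <- null_sigma_mc(w, n, statistic = "K", r = 25, n_null = 39,
                        seed = 5, self = TRUE)
    (ripley_K(p, "Macrophage", "Macrophage", 25) - nm$mean) / nm$sigma
  }, numeric(1))
  zs <- zs[!is.na(zs)]
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("cross-pair attraction and repulsion carry the expected signs", {
  w <- tme_window(0, 600, 0, 600)
  h <- lineage_hierarchy()
  lam <- setNames(c(2e-4, 2e-4), c(PH_TCELL, PH_MAC))
  sign_rate <- function(kind, stat, r, param) {
    hits <- 0; n_seeds <- 20
    for (s in seq_len(n_seeds)) {
      p <- do.call(simulate_cross_pair, c(list(
        kind, c(PH_TCELL, PH_MAC), lam, w, seed = 300 + s,
        hierarchy = h), param))
      ni <- p$n_by_type[["Tcell"]]; nj <- p$n_by_type[["Macrophage"]]
      if (ni < 1 || nj < 1) next
      nm <- null_sigma_mc(w, ni, nj, stat, r = r, n_null = 39, seed = 5)
      raw <- if (stat == "G") nearest_neighbor_G(p, "Tcell", "Macrophage", r)
             else ripley_K(p, "Tcell", "Macrophage", r)
      z <- (raw - nm$mean) / nm$sigma
      if (!is.na(z) && ((kind == "attraction" && z > 0) ||
                        (kind == "repulsion" && z < 0))) hits <- hits + 1
    }
    hits / n_seeds
  }
  expect_gte(sign_rate("attraction", "G", 10,
                       list(shared_fraction = 1, sigma = 10)), 0.9)
  expect_gte(sign_rate("repulsion", "K", 10, list(exclusion = 25)), 0.9)
  # shared fraction 0 -> independence: mean z(K) near 0 over seeds
  zs <- vapply(1:60, function(s) {
    p <- simulate_cross_pair("attraction", c(PH_TCELL, PH_MAC), lam, w,
                             shared_fraction = 0, sigma = 10,
                             seed = 500 + s, hierarchy = h)
    ni <- p$n_by_type[["Tcell"]]; nj <- p$n_by_type[["Macrophage"]]
    nm <- null_sigma_mc(w, ni, nj, "K", r = 10, n_null = 39, seed = 5)
    (ripley_K(p, "Tcell", "Macrophage", 10) - nm$mean) / nm$sigma
  }, numeric(1))
  zs <- zs[!is.na(zs)]
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("hard-core patterns respect the inhibition distance", {
  w <- tme_window(0, 600, 0, 600)
  p <- simulate_hardcore(PH_MAC, 2e-4, hardcore_dist = 25, w, seed = 9,
                         hierarchy = lineage_hierarchy())
  d <- nearest_distance_set(p, "Macrophage", "Macrophage")
  expect_true(all(d >= 25))
  expect_true(all(p$x >= 0 & p$x <= 600))
})

test_that("cohorts are seeded, matched in counts, and survival-structured", {
  co <- simulate_cohort(n_patients = 12, regions_per_patient = 2,
                        seed = 21, hierarchy = lineage_hierarchy())
  co2 <- simulate_cohort(n_patients = 12, regions_per_patient = 2,
                         seed = 21, hierarchy = lineage_hierarchy())
  expect_identical(co$survival, co2$survival)
  expect_identical(lapply(co$patterns, `[[`, "x"),
                   lapply(co2$patterns, `[[`, "x"))
  expect_true(all(co$survival$time_months > 0))
  expect_equal(as.vector(sort(table(co$groups))), c(6, 6))
  expect_error(simulate_cohort(n_patients = 2), "at least 4")
  expect_error(simulate_cohort(hazard_ratio = 0), "hazard_ratio")

  # matched expected counts between groups (within 3 SE over regions)
  co3 <- simulate_cohort(n_patients = 30, regions_per_patient = 2,
                         seed = 77, hierarchy = lineage_hierarchy())
  cnt <- vapply(co3$patterns, function(p) p$n_by_type[["Macrophage"]],
                numeric(1))
  grp <- co3$groups[vapply(co3$patterns, `[[`, "", "patient_id")]
  m <- tapply(cnt, grp, mean)
  pooled_se <- sqrt(sum(tapply(cnt, grp, var) / table(grp)))
  expect_lt(abs(m[["control"]] - m[["effect"]]), 3 * pooled_se)
})

test_that("log-rank power and null behave as designed", {
  # hazard_ratio 3, n = 60: p < 0.01 in >= 80% of seeds
  hits <- vapply(1:15, function(s) {
    co <- simulate_cohort(n_patients = 60, regions_per_patient = 0,
                          border_regions_per_patient = 0, hazard_ratio = 3,
                          seed = 700 + s, hierarchy = lineage_hierarchy())
    km <- km_logrank(co$groups, co$survival)
    km$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # hazard_ratio 1: p roughly uniform (KS not rejecting at 0.01)
  ps <- vapply(1:60, function(s) {
    co <- simulate_cohort(n_patients = 40, regions_per_patient = 0,
                          hazard_ratio = 1, followup_max = Inf,
                          seed = 900 + s, hierarchy = lineage_hierarchy())
    km_logrank(co$groups, co$survival)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
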