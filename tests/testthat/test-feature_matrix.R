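test_that("feature keys render uniquely and parse back", {
  h <- default_hierarchy()
  sc <- feature_schema(h)
  expect_false(anyDuplicated(sc$key) > 0)
  back <- parse_feature_key(sc$key)
  expect_identical(back$statistic, sc$statistic)
  expect_identical(back$type_i, sc$type_i)
  expect_identical(back$type_j, sc$type_j)
  expect_identical(back$radius, sc$radius)
  # class-prefixed render/parse
  k <- render_feature_key("K", "Tumor", "Tcell", 25, region_class = "border")
  expect_identical(parse_feature_key(k, region_class = TRUE)$statistic, "K")
})

test_that("the schema enumerates per-type and per-pair blocks", {
  # toy config: 2 types, both orderings configured
  h <- cell_type_hierarchy(
    type_map = list("PAX5+PD-L1-" = "Tumor", "CD3+CD8-PD-1-" = "Tcell",
                    "other" = character()),
    pairs = data.frame(type_i = c("Tumor", "Tcell"),
                       type_j = c("Tcell", "Tumor")))
  sc <- feature_schema(h)
  # per type: 3 scalars + F x6 + G*/K*/L* x6 = 27; per ordered pair:
  # 2 + 18; per unordered pair: 2. No spatial score (no Macrophage).
  expect_equal(nrow(sc), 2 * 27 + 2 * 20 + 1 * 2)
  expect_equal(sum(sc$statistic == "F"), 12)
  expect_equal(sum(sc$statistic %in% c("G", "K", "L") & sc$type_j == "*"), 36)
  expect_equal(sum(sc$statistic %in% c("G", "K", "L") & sc$type_j != "*"), 36)
  # the radius-based accounting: per type F x6 and per pair G/K/L x6 sum
  # to 24 features per "cell type (pair)" unit
  expect_equal(sum(sc$statistic == "F" & sc$type_i == "Tumor") +
               sum(sc$statistic %in% c("G", "K", "L") &
                   sc$type_i == "Tumor" & sc$type_j == "Tcell"), 24)
  # schema determinism
  expect_identical(sc, feature_schema(h))
  # lineage default: 3 lineages with spatial score present
  sc3 <- feature_schema(lineage_hierarchy())
  expect_equal(nrow(sc3), 3 * 27 + 9 * 20 + 6 * 2 + 2)
})

test_that("extract_region_features emits the whole schema, missing-aware", {
  h <- lineage_hierarchy()
  w <- tme_window(0, 200, 0, 200)
  cfg <- null_config(n_null = 19, grid_dim = c(10, 10), seed = 3)
  p <- random_pattern(20, 15, 10, w, seed = 1)
  fx <- extract_region_features(p, h, radii = c(10, 25), null_cfg = cfg)
  sc <- feature_schema(h, radii = c(10, 25))
  expect_identical(fx$key, sc$key)
  expect_true(all(!is.na(fx$value)))

  # remove macrophages: their statistics go missing, schema length fixed
  p2 <- random_pattern(20, 15, 0, w, seed = 1)
  fx2 <- extract_region_features(p2, h, radii = c(10, 25), null_cfg = cfg)
  expect_identical(fx2$key, sc$key)
  expect_true(all(is.na(fx2$value[grepl("Macrophage", fx2$key) &
                                  !fx2$statistic %in% c("ncount", "density")])))
  expect_equal(fx2$value[fx2$key == "ncount|Macrophage||"], 0)
  expect_equal(fx2$value[fx2$key == "density|Macrophage||"], 0)
  expect_true(is.na(fx2$value[fx2$key == "mss|||"]))

  # empty region: everything missing except nothing errors
  pe <- build_hierarchy_marks(cell_row(1, 1, PH_TUMOR)[0, ], h,
                              tme_window(0, 10, 0, 10))
  fxe <- extract_region_features(pe, h, radii = c(10, 25), null_cfg = cfg)
  expect_identical(fxe$key, sc$key)
  expect_true(all(is.na(fxe$value)))
})

test_that("same null config gives identical features; cache is transparent", {
  h <- lineage_hierarchy()
  p <- random_pattern(15, 12, 8, tme_window(0, 150, 0, 150), seed = 4)
  cfg1 <- null_config(n_null = 19, grid_dim = c(8, 8), seed = 7)
  cfg2 <- null_config(n_null = 19, grid_dim = c(8, 8), seed = 7,
                      cache = new.env(parent = emptyenv()))
  f1 <- extract_region_features(p, h, c(10, 25), cfg1)
  f2 <- extract_region_features(p, h, c(10, 25), cfg2)
  f3 <- extract_region_features(p, h, c(10, 25), cfg2) # cache hit pass
  expect_identical(f1$value, f2$value)
  expect_identical(f2$value, f3$value)
})

test_that("aggregation averages per patient/class ignoring missing", {
  sc_key <- c("ncount|Tumor||", "mmd|Tumor|Tcell|")
  mk <- function(pid, cls, rid, v) data.frame(
    statistic = c("ncount", "mmd"), type_i = "Tumor",
    type_j = c(NA, "Tcell"), radius = NA, key = sc_key, value = v,
    patient_id = pid, region_id = rid, region_class = cls,
    stringsAsFactors = FALSE)
  feats <- list(mk("A", "tumor", "r1", c(0.2, 5)),
                mk("A", "tumor", "r2", c(NA, 7)),
                mk("A", "tumor", "r3", c(0.4, NA)),
                mk("B", "tumor", "r4", c(0.5, NA)),
                mk("B", "border", "r5", c(0.1, 3)))
  m <- aggregate_patient_features(feats)
  expect_equal(m$tumor["A", "ncount|Tumor||"], 0.3) # mean of 0.2, NA, 0.4
  expect_equal(m$tumor["A", "mmd|Tumor|Tcell|"], 6)
  expect_true(is.na(m$tumor["B", "mmd|Tumor|Tcell|"])) # all-missing
  expect_equal(m$tumor["B", "ncount|Tumor||"], 0.5) # single region passthrough
  # patient A has no border regions -> fully missing border row
  expect_true(all(is.na(m$border["A", ])))
  expect_equal(m$border["B", "mmd|Tumor|Tcell|"], 3)
  # region order invariance
  m2 <- aggregate_patient_features(rev(feats))
  expect_identical(m$tumor[rownames(m2$tumor), colnames(m2$tumor)], m2$tumor)
})

test_that("filtering drops <= 50%-observed features and imputes medians", {
  set.seed(1)
  n <- 88
  m <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("P%02d", 1:n), c("a", "b", "c")))
  m[45:88, "a"] <- NA # observed in 44 of 88 -> dropped (not > 50%)
  m[46:88, "b"] <- NA # observed in 45 -> retained, imputed
  out <- filter_and_impute(m)
  expect_identical(colnames(out), c("b", "c"))
  expect_identical(attr(out, "dropped"), "a")
  expect_false(anyNA(out))
  expect_equal(unique(out[46:88, "b"]), median(m[1:45, "b"]))
  expect_identical(out[, "c"], m[, "c"]) # fully observed: unchanged
  # even-count median = mean of the central pair
  m2 <- cbind(x = c(1, 2, 100, NA), y = 1:4)
  rownames(m2) <- paste0("p", 1:4)
  out2 <- filter_and_impute(m2)
  expect_equal(out2["p4", "x"], 2)
  expect_error(filter_and_impute(m2[1:1, , drop = FALSE]), "patients")
  m3 <- cbind(x = c(1, NA, NA, NA), y = c(NA, NA, 1, 2))
  rownames(m3) <- paste0("p", 1:4)
  expect_error(filter_and_impute(m3), "no feature")
})

test_that("feature matrices round-trip through TSV", {
  m <- matrix(c(1.25, NA, 3, 4.5), 2, 2,
              dimnames = list(c("A", "B"),
                              c("K|Tumor|Tcell|r25", "ncount|Tumor||")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(m, f, extra = list(region_class = "tumor"))
  back <- read_feature_matrix(f)
  expect_equal(back, m)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$n_features, 2)
  expect_equal(side$region_class, "tumor")
})
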