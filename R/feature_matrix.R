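# Feature schema enumeration, per-region extraction, patient-level
# aggregation, missingness filtering and median imputation.

#' Render a feature key
#'
#' Keys are `|`-separated: `statistic|type_i|type_j|r<radius>` with empty
#' slots for absent fields, optionally prefixed by the region class. Cell
#' type names never contain `|`, so rendering is unique and reversible.
#'
#' @param statistic Statistic name (e.g. `"K"`, `"mmd"`, `"ncount"`).
#' @param type_i,type_j Cell types (`type_j` may be `"*"` or `NA`).
#' @param radius Radius in um or `NA`.
#' @param region_class Optional `"tumor"`/`"border"` prefix.
#' @return Character key(s).
#' @export
render_feature_key <- function(statistic, type_i = NA, type_j = NA,
                               radius = NA, region_class = NULL) {
  k <- paste(statistic,
             ifelse(is.na(type_i), "", type_i),
             ifelse(is.na(type_j), "", type_j),
             ifelse(is.na(radius), "", paste0("r", radius)),
             sep = "|")
  if (!is.null(region_class)) k <- paste(region_class, k, sep = "|")
  k
}

#' Parse feature keys back into their fields
#'
#' @param key Character vector of rendered keys (without class prefix, or
#'   with one if `region_class = TRUE`).
#' @param region_class Do the keys carry a region-class prefix?
#' @return Data frame with the key fields.
#' @export
parse_feature_key <- function(key, region_class = FALSE) {
  parts <- strsplit(key, "|", fixed = TRUE)
  off <- if (region_class) 1L else 0L
  out <- data.frame(
    statistic = vapply(parts, `[`, "", off + 1L),
    type_i = vapply(parts, `[`, "", off + 2L),
    type_j = vapply(parts, `[`, "", off + 3L),
    radius = suppressWarnings(
      as.numeric(sub("^r", "", vapply(parts, `[`, "", off + 4L)))),
    stringsAsFactors = FALSE)
  if (region_class)
    out <- cbind(data.frame(region_class = vapply(parts, `[`, "", 1L),
                            stringsAsFactors = FALSE), out)
  out$type_i[out$type_i == ""] <- NA_character_
  out$type_j[out$type_j == ""] <- NA_character_
  out
}

# unordered pairs of a pair list, in first-occurrence order
.unordered_pairs <- function(pairs) {
  a <- pmin(pairs$type_i, pairs$type_j)
  b <- pmax(pairs$type_i, pairs$type_j)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(type_i = a[keep], type_j = b[keep], stringsAsFactors = FALSE)
}

#' Enumerate the feature schema
#'
#' Deterministic ordered list of feature keys implied by a hierarchy and a
#' radius set: per type the normalized count, density, chi-squared and the
#' standardized F plus the `"*"`-variant G/K/L at every radius; per ordered
#' pair MMD/MADMD and standardized G/K/L at every radius; per unordered
#' pair MD/MADD; plus the median spatial score and its MAD when all three
#' lineages are present. This realizes the "4 functions x 6 radii = 24 per
#' cell type (pair)" accounting: F is type-level (6), G/K/L are pair-level
#' (18).
#'
#' @param hierarchy A [cell_type_hierarchy()].
#' @param radii Radii in um (default 5, 10, 25, 50, 75, 100).
#' @return Data frame `statistic`, `type_i`, `type_j`, `radius`, `key`.
#' @export
feature_schema <- function(hierarchy, radii = c(5, 10, 25, 50, 75, 100)) {
  if (is.unsorted(radii, strictly = TRUE) || any(radii <= 0))
    stop_("radii must be strictly increasing and positive")
  rows <- list()
  add <- function(statistic, type_i = NA, type_j = NA, radius = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, type_i = type_i, type_j = type_j,
      radius = radius, stringsAsFactors = FALSE)
  }
  for (t in hierarchy$types) {
    add(c("ncount", "density", "chi2"), t)
    add("F", t, radius = radii)
    for (s in c("G", "K", "L")) add(s, t, "*", radii)
  }
  for (p in seq_len(nrow(hierarchy$pairs))) {
    ti <- hierarchy$pairs$type_i[p]; tj <- hierarchy$pairs$type_j[p]
    add(c("mmd", "madmd"), ti, tj)
    for (s in c("G", "K", "L")) add(s, ti, tj, radii)
  }
  up <- .unordered_pairs(hierarchy$pairs)
  for (p in seq_len(nrow(up)))
    add(c("md", "madd"), up$type_i[p], up$type_j[p])
  if (all(c("Tumor", "Tcell", "Macrophage") %in% hierarchy$types))
    add(c("mss", "madss"))
  out <- do.call(rbind, rows)
  out$key <- render_feature_key(out$statistic, out$type_i, out$type_j,
                                out$radius)
  rownames(out) <- NULL
  out
}

# fetch (and cache) the G/K/L null models of a pair of counts
.null_pair_cached <- function(cache, window, n_i, n_j, self, radii, cfg) {
  key <- sprintf("pair|%g|%g|%d|%d|%d", window$xmax - window$xmin,
                 window$ymax - window$ymin, n_i, n_j, self)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  seed <- derive_seed(cfg$seed, key)
  nm <- null_pair_models(window, n_i, n_j, radii, cfg$n_null, seed, self)
  if (!is.null(cache)) cache[[key]] <- nm
  nm
}

.null_F_cached <- function(cache, window, n_i, radii, cfg) {
  key <- sprintf("F|%g|%g|%d", window$xmax - window$xmin,
                 window$ymax - window$ymin, n_i)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  seed <- derive_seed(cfg$seed, key)
  nm <- null_F_model(window, n_i, radii, cfg$n_null, seed, cfg$grid_dim)
  if (!is.null(cache)) cache[[key]] <- nm
  nm
}

# standardized G/K/L block for one (i, j) pairing given coordinate sets
.std_pair_block <- function(pattern, ci, cj, self, radii, cfg, cache) {
  nr <- length(radii)
  out <- list(G = rep(NA_real_, nr), K = rep(NA_real_, nr),
              L = rep(NA_real_, nr))
  n_i <- length(ci$x); n_j <- length(cj$x)
  if (n_i == 0L || n_j == 0L) return(out)
  if (self && n_i < 2L) return(out)
  w <- pattern$window
  nm <- .null_pair_cached(cache, w, n_i, n_j, self, radii, cfg)
  lambda_j <- n_j / w$area
  g_raw <- .raw_G(ci$x, ci$y, ci$id, cj$x, cj$y, cj$id, radii)
  k_raw <- .raw_K(w$area, ci$x, ci$y, ci$id, cj$x, cj$y, cj$id, radii)
  l_raw <- sqrt(k_raw / pi)
  center <- function(stat, theo)
    if (cfg$center == "null") nm[[stat]]$mean else theo
  out$G <- standardize_statistic(
    g_raw, center("G", theoretical_baseline("G", lambda_j, radii)),
    nm$G$sigma)
  out$K <- standardize_statistic(
    k_raw, center("K", theoretical_baseline("K", r = radii)), nm$K$sigma)
  out$L <- standardize_statistic(
    l_raw, center("L", theoretical_baseline("L", r = radii)), nm$L$sigma)
  out
}

#' Extract the full feature vector of one region
#'
#' Computes every statistic in the schema for one region pattern;
#' statistics whose preconditions fail are emitted as `NA` so the result
#' always has the full schema length.
#'
#' @param pattern A `region_pattern`.
#' @param hierarchy A [cell_type_hierarchy()].
#' @param radii Radii in um.
#' @param null_cfg A [null_config()]; its seed fixes the Monte-Carlo
#'   standardization, its `cache` environment (if any) reuses null models
#'   across regions with identical window dimensions and counts.
#' @return Data frame: schema columns plus `value`, `patient_id`,
#'   `region_id`, `region_class`.
#' @export
extract_region_features <- function(pattern, hierarchy = default_hierarchy(),
                                    radii = c(5, 10, 25, 50, 75, 100),
                                    null_cfg = null_config()) {
  schema <- feature_schema(hierarchy, radii)
  vals <- setNames(rep(NA_real_, nrow(schema)), schema$key)
  finish <- function() {
    out <- schema
    out$value <- unname(vals[schema$key])
    out$patient_id <- pattern$patient_id
    out$region_id <- pattern$region_id
    out$region_class <- pattern$region_class
    out
  }
  # an empty region defines nothing, not even zero counts
  if (pattern$n_total == 0L) return(finish())
  cfg <- null_cfg
  cache <- cfg$cache %||% new.env(parent = emptyenv())
  w <- pattern$window
  set_val <- function(statistic, type_i = NA, type_j = NA, radius = NA, v) {
    vals[render_feature_key(statistic, type_i, type_j, radius)] <<- v
  }

  for (t in hierarchy$types) {
    ci <- type_coords(pattern, t)
    n_i <- length(ci$x)
    set_val("ncount", t, v = normalized_count(pattern, t))
    set_val("density", t, v = cell_density(pattern, t))
    set_val("chi2", t, v = chi_squared_inhomogeneity(pattern, t))
    if (n_i >= 1L) {
      nmF <- .null_F_cached(cache, w, n_i, radii, cfg)
      f_raw <- .raw_F(w, ci$x, ci$y, radii, cfg$grid_dim)
      f_base <- if (cfg$center == "null") nmF$mean else
        theoretical_baseline("F", n_i / w$area, radii)
      set_val("F", t, radius = radii,
              v = standardize_statistic(f_raw, f_base, nmF$sigma))
    }
    cs <- type_coords(pattern, "*", exclude = t)
    blk <- .std_pair_block(pattern, ci, cs, self = FALSE, radii, cfg, cache)
    for (s in c("G", "K", "L"))
      set_val(s, t, "*", radii, v = blk[[s]])
  }

  for (p in seq_len(nrow(hierarchy$pairs))) {
    ti <- hierarchy$pairs$type_i[p]; tj <- hierarchy$pairs$type_j[p]
    lds <- local_distance_stats(pattern, ti, tj, cfg$mad_constant)
    set_val("mmd", ti, tj, v = lds[["mmd"]])
    set_val("madmd", ti, tj, v = lds[["madmd"]])
    ci <- type_coords(pattern, ti)
    cj <- type_coords(pattern, tj, exclude = NULL)
    self <- identical(ti, tj)
    if (self) cj <- ci
    blk <- .std_pair_block(pattern, ci, cj, self, radii, cfg, cache)
    for (s in c("G", "K", "L"))
      set_val(s, ti, tj, radii, v = blk[[s]])
  }

  up <- .unordered_pairs(hierarchy$pairs)
  for (p in seq_len(nrow(up))) {
    gds <- global_distance_stats(pattern, up$type_i[p], up$type_j[p],
                                 cfg$mad_constant)
    set_val("md", up$type_i[p], up$type_j[p], v = gds[["md"]])
    set_val("madd", up$type_i[p], up$type_j[p], v = gds[["madd"]])
  }

  if (all(c("Tumor", "Tcell", "Macrophage") %in% hierarchy$types)) {
    ss <- spatial_score_stats(pattern, cfg$mad_constant)
    set_val("mss", v = ss[["mss"]])
    set_val("madss", v = ss[["madss"]])
  }

  finish()
}

#' Aggregate region features to patient level
#'
#' Per patient, region class and feature key: the unweighted mean over
#' that patient's regions of that class, ignoring missing values; a
#' feature missing in every region (or a patient without regions of a
#' class) stays missing.
#'
#' @param region_features List of [extract_region_features()] results, or
#'   one long data frame row-binding them.
#' @return Named list of patient x feature matrices, one per region class
#'   present; every matrix has the same row set (all patients seen).
#' @export
aggregate_patient_features <- function(region_features) {
  long <- if (is.data.frame(region_features)) region_features
          else do.call(rbind, region_features)
  patients <- unique(long$patient_id)
  out <- list()
  for (cl in intersect(c("tumor", "border"), unique(long$region_class))) {
    sub <- long[long$region_class == cl, , drop = FALSE]
    keys <- unique(sub$key) # schema order preserved within a class
    m <- matrix(NA_real_, length(patients), length(keys),
                dimnames = list(patients, keys))
    agg <- tapply(sub$value, list(sub$patient_id, sub$key),
                  function(v) if (all(is.na(v))) NA_real_
                              else mean(v, na.rm = TRUE))
    m[rownames(agg), colnames(agg)] <- agg
    m <- m[, keys, drop = FALSE] # tapply sorts; restore schema order
    out[[cl]] <- m
  }
  out
}

#' Filter features by missingness and impute the rest
#'
#' Drops features observed in 50% of patients or fewer (strictly more than
#' half must be observed to retain) and replaces the remaining missing
#' entries by the per-feature median over observed patients. Output is
#' dense.
#'
#' @param mat Patient x feature matrix with `NA` for missing.
#' @return The filtered, imputed matrix; attribute `"dropped"` lists the
#'   removed feature keys.
#' @export
filter_and_impute <- function(mat) {
  if (nrow(mat) < 2L) stop_("filter_and_impute needs >= 2 patients")
  observed <- colSums(!is.na(mat))
  keep <- observed > nrow(mat) / 2
  if (!any(keep))
    stop_("no feature observed in more than half of the patients")
  dropped <- colnames(mat)[!keep]
  mat <- mat[, keep, drop = FALSE]
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    if (anyNA(v)) mat[is.na(v), j] <- median(v, na.rm = TRUE)
  }
  attr(mat, "dropped") <- dropped
  mat
}

#' Write a patient x feature matrix as TSV with a JSON sidecar
#'
#' @param mat Patient x feature matrix.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param extra Named list merged into the sidecar (config hash etc.).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(mat, path, extra = list()) {
  df <- data.frame(patient_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(n_patients = nrow(mat), n_features = ncol(mat),
                 features = colnames(mat),
                 missing_per_feature = unname(colSums(is.na(mat))),
                 dropped = attr(mat, "dropped") %||% character(0)),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a patient x feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return Patient x feature numeric matrix.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
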