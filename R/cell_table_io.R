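# Cell-table parsing, observation windows and region patterns.

#' Rectangular observation window
#'
#' @param xmin,xmax,ymin,ymax Window bounds in micrometers.
#' @return An object of class `tme_window` with an `area` field (um^2).
#' @export
tme_window <- function(xmin, xmax, ymin, ymax) {
  stopifnot(is.finite(xmin), is.finite(xmax), is.finite(ymin), is.finite(ymax))
  if (xmax <= xmin || ymax <= ymin)
    stop_("degenerate window: need xmax > xmin and ymax > ymin")
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 area = (xmax - xmin) * (ymax - ymin)),
            class = "tme_window")
}

#' @export
print.tme_window <- function(x, ...) {
  cat(sprintf("tme_window [%g, %g] x [%g, %g] um, area %g um^2\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$area))
  invisible(x)
}

#' Infer an observation window from cell coordinates
#'
#' Axis-aligned bounding box of the coordinates, expanded by `padding` on
#' each side. Exported cell tables do not carry the imaged-region
#' dimensions, so the bounding box is the deterministic fallback; a window
#' declared in metadata should be preferred when available.
#'
#' @param cells Data frame with numeric `x`, `y` columns (um).
#' @param padding Expansion per side (um), default 0.
#' @return A [tme_window()].
#' @export
infer_window <- function(cells, padding = 0) {
  if (nrow(cells) == 0L) stop_("cannot infer a window from zero cells")
  tme_window(min(cells$x) - padding, max(cells$x) + padding,
             min(cells$y) - padding, max(cells$y) + padding)
}

.required_cols <- c("x", "y", "phenotype", "region_id", "region_class",
                    "patient_id")

#' Parse a per-region cell table
#'
#' Reads a delimited text file with one row per cell and validates it
#' against the closed phenotype label set. Column names in the file are
#' mapped to the required fields through `columns`, so arbitrary export
#' headers can be consumed without rewriting files.
#'
#' @param path Path to the delimited file.
#' @param columns Named character vector mapping required field ->
#'   file column name. Defaults to identity naming.
#' @param sep Field delimiter, default `","`.
#' @return Data frame of cell records (columns `x`, `y`, `phenotype`,
#'   `region_id`, `region_class`, `patient_id`), row order preserved.
#' @export
parse_cell_table <- function(path, columns = NULL, sep = ",") {
  if (!file.exists(path)) stop_("cell table not found: %s", path)
  columns <- columns %||% setNames(.required_cols, .required_cols)
  missing_map <- setdiff(.required_cols, names(columns))
  if (length(missing_map))
    stop_("column mapping lacks required field(s): %s",
          paste(missing_map, collapse = ", "))
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  absent <- setdiff(unname(columns[.required_cols]), names(raw))
  if (length(absent))
    stop_("cell table %s lacks column(s): %s", path,
          paste(absent, collapse = ", "))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    x = raw[[columns[["x"]]]],
                    y = raw[[columns[["y"]]]],
                    phenotype = raw[[columns[["phenotype"]]]],
                    region_id = raw[[columns[["region_id"]]]],
                    region_class = raw[[columns[["region_class"]]]],
                    patient_id = raw[[columns[["patient_id"]]]])
  if (nrow(out) == 0L) {
    out$x <- numeric(0); out$y <- numeric(0)
    return(out)
  }
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop_("non-numeric %s coordinate in %s at row(s): %s", cc, path,
            paste(utils::head(bad, 5), collapse = ", "))
    out[[cc]] <- v
  }
  unknown <- setdiff(unique(out$phenotype), tme_phenotypes())
  if (length(unknown))
    stop_("unknown phenotype label(s) in %s: %s", path,
          paste(unknown, collapse = ", "))
  bad_class <- setdiff(unique(out$region_class), c("tumor", "border"))
  if (length(bad_class))
    stop_("region_class must be 'tumor' or 'border'; found: %s",
          paste(bad_class, collapse = ", "))
  out
}

#' Write a cell table in the CSV dialect `parse_cell_table()` reads
#'
#' @param cells Cell-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  write.csv(cells[, .required_cols, drop = FALSE], path, row.names = FALSE,
            quote = TRUE)
  invisible(path)
}

#' Attach hierarchy marks and build a region pattern
#'
#' Turns validated cell records of one region into a marked point pattern:
#' each cell carries the full set of analysis-type marks implied by its raw
#' phenotype (a CD3+CD8+PD-1+ cell is simultaneously a Tcell, a CD8+ Tcell
#' and a CD3+CD8+PD1+ Tcell; "other" cells carry no marks but still count
#' towards the total).
#'
#' @param cells Cell-record data frame for a single region.
#' @param hierarchy A [cell_type_hierarchy()].
#' @param window A [tme_window()]; defaults to [infer_window()] of `cells`.
#' @return An object of class `region_pattern` with fields `x`, `y`,
#'   `phenotype`, `marks` (logical cells x types matrix), `window`,
#'   `region_id`, `region_class`, `patient_id`, `n_by_type`, `n_total`.
#' @export
build_hierarchy_marks <- function(cells, hierarchy = default_hierarchy(),
                                  window = NULL) {
  n <- nrow(cells)
  if (n > 0L) {
    for (f in c("region_id", "region_class", "patient_id"))
      if (length(unique(cells[[f]])) != 1L)
        stop_("cells of one region must share %s", f)
    unknown <- setdiff(unique(cells$phenotype), names(hierarchy$type_map))
    if (length(unknown))
      stop_("phenotype(s) missing from hierarchy type_map: %s",
            paste(unknown, collapse = ", "))
  }
  window <- window %||% infer_window(cells)
  if (n > 0L) {
    outside <- which(cells$x < window$xmin | cells$x > window$xmax |
                     cells$y < window$ymin | cells$y > window$ymax)
    if (length(outside))
      stop_("cell(s) outside window at index: %s",
            paste(utils::head(outside, 5), collapse = ", "))
  }
  types <- hierarchy$types
  marks <- matrix(FALSE, nrow = n, ncol = length(types),
                  dimnames = list(NULL, types))
  if (n > 0L)
    for (ph in unique(cells$phenotype)) {
      ty <- intersect(hierarchy$type_map[[ph]], types)
      if (length(ty)) marks[cells$phenotype == ph, ty] <- TRUE
    }
  structure(list(
    x = if (n) cells$x else numeric(0),
    y = if (n) cells$y else numeric(0),
    phenotype = if (n) cells$phenotype else character(0),
    marks = marks,
    window = window,
    region_id = if (n) cells$region_id[1] else NA_character_,
    region_class = if (n) cells$region_class[1] else NA_character_,
    patient_id = if (n) cells$patient_id[1] else NA_character_,
    n_by_type = colSums(marks),
    n_total = n
  ), class = "region_pattern")
}

#' @export
print.region_pattern <- function(x, ...) {
  cat(sprintf("region_pattern '%s' (%s, patient %s): %d cells\n",
              x$region_id, x$region_class, x$patient_id, x$n_total))
  nz <- x$n_by_type[x$n_by_type > 0]
  if (length(nz))
    cat("  ", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

# Coordinates of cells carrying mark `type`; type = "*" with `exclude`
# gives all cells NOT carrying mark `exclude` ("all cells of type unequal
# to i", which includes unmarked "other" cells). Returns list(x, y, id).
type_coords <- function(pattern, type, exclude = NULL) {
  if (identical(type, "*")) {
    keep <- if (is.null(exclude)) rep(TRUE, pattern$n_total)
            else !pattern$marks[, exclude]
  } else {
    if (!type %in% colnames(pattern$marks))
      stop_("type '%s' not in pattern hierarchy", type)
    keep <- pattern$marks[, type]
  }
  idx <- which(keep)
  list(x = pattern$x[idx], y = pattern$y[idx], id = idx)
}

#' Convert cell records of (possibly) many regions into region patterns
#'
#' Splits on (patient_id, region_id, region_class) and builds one pattern
#' per region.
#'
#' @param cells Cell-record data frame.
#' @param hierarchy A [cell_type_hierarchy()].
#' @param window Optional shared [tme_window()]; default infers per region.
#' @param padding Bounding-box padding (um) when inferring windows.
#' @return List of `region_pattern` objects.
#' @export
split_regions <- function(cells, hierarchy = default_hierarchy(),
                          window = NULL, padding = 0) {
  key <- paste(cells$patient_id, cells$region_id, cells$region_class,
               sep = "\r")
  lapply(split(seq_len(nrow(cells)), key), function(idx) {
    cc <- cells[idx, , drop = FALSE]
    w <- window %||% infer_window(cc, padding = padding)
    build_hierarchy_marks(cc, hierarchy, w)
  })
}
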