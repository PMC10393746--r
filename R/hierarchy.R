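# Cell-type vocabulary: 10 raw phenotypes called by the upstream classifier
# and the 13 analysis cell types they roll up into (three lineages, each
# split by PD-L1 or CD8/PD-1 status).

#' Raw phenotype labels
#'
#' The closed set of ten phenotype labels assigned per cell by the upstream
#' image-analysis classifier. Cell tables must use these labels verbatim.
#'
#' @return Character vector of the 10 raw phenotype labels.
#' @export
tme_phenotypes <- function() {
  c("PAX5+PD-L1-", "PAX5+PD-L1+",
    "CD163+PD-L1-", "CD163+PD-L1+",
    "CD3+CD8-PD-1-", "CD3+CD8+PD-1-", "CD3+CD8-PD-1+", "CD3+CD8+PD-1+",
    "other PD-L1+", "other")
}

#' Analysis cell types
#'
#' The 13 analysis cell types: the three lineages (Tumor, Tcell,
#' Macrophage) plus their marker-defined subtypes. A single cell can carry
#' several of these marks at once (a CD3+CD8+PD-1+ cell is a Tcell, a
#' CD8+ Tcell and a CD3+CD8+PD1+ Tcell).
#'
#' @return Character vector of the 13 analysis cell-type names.
#' @export
tme_cell_types <- function() {
  c("Macrophage", "PDL1- Macrophage", "PDL1+ Macrophage",
    "Tcell", "CD8- Tcell", "CD8+ Tcell",
    "CD3+CD8-PD1- Tcell", "CD3+CD8-PD1+ Tcell",
    "CD3+CD8+PD1- Tcell", "CD3+CD8+PD1+ Tcell",
    "Tumor", "PDL1- Tumor", "PDL1+ Tumor")
}

.default_type_map <- function() {
  list(
    "PAX5+PD-L1-"   = c("Tumor", "PDL1- Tumor"),
    "PAX5+PD-L1+"   = c("Tumor", "PDL1+ Tumor"),
    "CD163+PD-L1-"  = c("Macrophage", "PDL1- Macrophage"),
    "CD163+PD-L1+"  = c("Macrophage", "PDL1+ Macrophage"),
    "CD3+CD8-PD-1-" = c("Tcell", "CD8- Tcell", "CD3+CD8-PD1- Tcell"),
    "CD3+CD8+PD-1-" = c("Tcell", "CD8+ Tcell", "CD3+CD8+PD1- Tcell"),
    "CD3+CD8-PD-1+" = c("Tcell", "CD8- Tcell", "CD3+CD8-PD1+ Tcell"),
    "CD3+CD8+PD-1+" = c("Tcell", "CD8+ Tcell", "CD3+CD8+PD1+ Tcell"),
    "other PD-L1+"  = character(),
    "other"         = character()
  )
}

#' All ordered pairs of the three lineage types
#'
#' Default cell-type pair list: the nine ordered pairs (self-pairs
#' included) among Tumor, Tcell and Macrophage. The cohort study this
#' package models evaluated a larger, hand-curated pair set that was never
#' published as a list; this default is the documented approximation and is
#' fully user-overridable through [cell_type_hierarchy()].
#'
#' @param types Character vector of types to pair (default the three
#'   lineages).
#' @param self Include self-pairs (i, i)? Default `TRUE`.
#' @return Data frame with columns `type_i`, `type_j`.
#' @export
lineage_pairs <- function(types = c("Tumor", "Tcell", "Macrophage"),
                          self = TRUE) {
  g <- expand.grid(type_j = types, type_i = types,
                   stringsAsFactors = FALSE)[, c("type_i", "type_j")]
  if (!self) g <- g[g$type_i != g$type_j, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Construct a cell-type hierarchy
#'
#' Bundles the raw-phenotype to analysis-type mapping with the ordered list
#' of cell-type pairs for which pairwise statistics are computed.
#'
#' @param type_map Named list: raw phenotype label -> character vector of
#'   analysis types (possibly empty). Names must be drawn from
#'   [tme_phenotypes()]; every mapped type must be in [tme_cell_types()].
#' @param pairs Data frame with columns `type_i`, `type_j` (ordered pairs,
#'   self-pairs allowed, no duplicates). Directional statistics (G, K, L,
#'   MMD, MADMD) are emitted per ordered pair; symmetric ones (MD, MADD)
#'   once per unordered pair.
#' @param types Analysis types in schema order; defaults to the types that
#'   occur in `type_map`, ordered as in [tme_cell_types()].
#' @return An object of class `cell_type_hierarchy`.
#' @export
cell_type_hierarchy <- function(type_map = .default_type_map(),
                                pairs = lineage_pairs(),
                                types = NULL) {
  canon_ph <- tme_phenotypes()
  canon_ty <- tme_cell_types()
  bad_ph <- setdiff(names(type_map), canon_ph)
  if (length(bad_ph))
    stop_("unknown phenotype label(s) in type_map: %s",
          paste(bad_ph, collapse = ", "))
  mapped <- unique(unlist(type_map, use.names = FALSE))
  bad_ty <- setdiff(mapped, canon_ty)
  if (length(bad_ty))
    stop_("unknown analysis type(s) in type_map: %s",
          paste(bad_ty, collapse = ", "))
  if (is.null(types)) types <- canon_ty[canon_ty %in% mapped]
  if (length(setdiff(types, canon_ty)))
    stop_("types must be a subset of tme_cell_types()")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("type_i", "type_j") %in% names(pairs)))
    stop_("pairs must have columns type_i, type_j")
  pk <- paste(pairs$type_i, pairs$type_j, sep = "\r")
  if (anyDuplicated(pk)) stop_("duplicated pairs in pair list")
  bad_pair <- setdiff(unique(c(pairs$type_i, pairs$type_j)), types)
  if (length(bad_pair))
    stop_("pair list uses type(s) absent from the hierarchy: %s",
          paste(bad_pair, collapse = ", "))
  structure(list(type_map = type_map, pairs = pairs, types = types),
            class = "cell_type_hierarchy")
}

#' Default hierarchy: 10 phenotypes, 13 types, lineage pair list
#'
#' @param pairs Pair list, defaults to [lineage_pairs()].
#' @return A `cell_type_hierarchy`.
#' @export
default_hierarchy <- function(pairs = lineage_pairs()) {
  cell_type_hierarchy(.default_type_map(), pairs)
}

#' A reduced three-type hierarchy for fast simulation-based testing
#'
#' Maps one representative phenotype onto each lineage (Tumor, Tcell,
#' Macrophage) and pairs the lineages. Feature schemas built on it are an
#' order of magnitude smaller than the 13-type default, which keeps
#' Monte-Carlo-heavy tests inside tight time budgets.
#'
#' @param pairs Pair list, defaults to [lineage_pairs()].
#' @return A `cell_type_hierarchy` over the three lineage types.
#' @export
lineage_hierarchy <- function(pairs = lineage_pairs()) {
  cell_type_hierarchy(
    type_map = list(
      "PAX5+PD-L1-"   = "Tumor",
      "PAX5+PD-L1+"   = "Tumor",
      "CD163+PD-L1-"  = "Macrophage",
      "CD163+PD-L1+"  = "Macrophage",
      "CD3+CD8-PD-1-" = "Tcell",
      "CD3+CD8+PD-1-" = "Tcell",
      "CD3+CD8-PD-1+" = "Tcell",
      "CD3+CD8+PD-1+" = "Tcell",
      "other PD-L1+"  = character(),
      "other"         = character()
    ),
    pairs = pairs
  )
}

#' Read a hierarchy from a JSON config file
#'
#' The file holds an object with fields `type_map` (phenotype -> array of
#' types), `pairs` (array of two-element arrays) and optionally `types`.
#'
#' @param path Path to the JSON file.
#' @return A `cell_type_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- lapply(cfg$type_map, function(v) as.character(unlist(v)))
  pairs <- cfg$pairs
  if (is.matrix(pairs))
    pairs <- data.frame(type_i = pairs[, 1], type_j = pairs[, 2],
                        stringsAsFactors = FALSE)
  cell_type_hierarchy(type_map = tm, pairs = pairs,
                      types = cfg$types %||% NULL)
}

#' @export
print.cell_type_hierarchy <- function(x, ...) {
  cat("cell_type_hierarchy:", length(x$types), "analysis types,",
      length(x$type_map), "raw phenotypes,", nrow(x$pairs),
      "ordered pairs\n")
  invisible(x)
}
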