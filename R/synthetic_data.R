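# Simulators for marked point patterns with known spatial structure and
# synthetic cohorts with survival, so every downstream stage is testable
# without external data.

# assemble a region_pattern from phenotype-labelled coordinates
.make_pattern <- function(x, y, phenotype, window, hierarchy,
                          region_id, region_class, patient_id) {
  n <- length(x)
  cells <- data.frame(x = x, y = y, phenotype = phenotype,
                      region_id = rep(region_id, n),
                      region_class = rep(region_class, n),
                      patient_id = rep(patient_id, n),
                      stringsAsFactors = FALSE)
  p <- build_hierarchy_marks(cells, hierarchy, window)
  # keep region metadata even for empty simulated patterns
  p$region_id <- region_id
  p$region_class <- region_class
  p$patient_id <- patient_id
  p
}

#' Simulate complete spatial randomness (CSR)
#'
#' Each phenotype is an independent homogeneous Poisson process: Poisson
#' counts with mean `intensity * area` and uniform positions. Passing
#' `counts` fixes the per-phenotype counts instead (binomial process), the
#' conditioning used by the standardization null.
#'
#' @param intensity Named numeric: phenotype label -> intensity (per um^2).
#' @param window A [tme_window()].
#' @param counts Optional named integer vector of fixed counts overriding
#'   the Poisson draw.
#' @param seed Seed; identical seeds give identical patterns.
#' @param hierarchy Hierarchy used to mark the cells.
#' @param region_id,region_class,patient_id Region metadata.
#' @return A `region_pattern`.
#' @export
simulate_csr <- function(intensity, window, counts = NULL, seed = NULL,
                         hierarchy = default_hierarchy(),
                         region_id = "sim", region_class = "tumor",
                         patient_id = "sim") {
  if (window$area <= 0) stop_("zero-area window")
  if (any(intensity < 0)) stop_("intensities must be >= 0")
  with_seed(seed, {
    xs <- ys <- numeric(0); ph <- character(0)
    for (p in names(intensity)) {
      n <- if (!is.null(counts)) counts[[p]] %||% 0L
           else rpois(1, intensity[[p]] * window$area)
      if (n > 0) {
        u <- .runif_window(n, window)
        xs <- c(xs, u$x); ys <- c(ys, u$y); ph <- c(ph, rep(p, n))
      }
    }
    .make_pattern(xs, ys, ph, window, hierarchy, region_id, region_class,
                  patient_id)
  })
}

# Thomas-type offspring around given parents; offspring falling outside
# the window are re-drawn (not clipped) to preserve intensity, which
# slightly shrinks the effective cluster spread near edges.
.thomas_offspring <- function(px, py, mean_offspring, sigma, window,
                              max_tries = 50) {
  xs <- ys <- numeric(0)
  for (k in seq_along(px)) {
    n <- rpois(1, mean_offspring)
    for (o in seq_len(n)) {
      ok <- FALSE
      for (tr in seq_len(max_tries)) {
        ox <- px[k] + rnorm(1, 0, sigma)
        oy <- py[k] + rnorm(1, 0, sigma)
        if (ox >= window$xmin && ox <= window$xmax &&
            oy >= window$ymin && oy <= window$ymax) { ok <- TRUE; break }
      }
      if (!ok) { u <- .runif_window(1, window); ox <- u$x; oy <- u$y }
      xs <- c(xs, ox); ys <- c(ys, oy)
    }
  }
  list(x = xs, y = ys)
}

#' Simulate a Thomas cluster process for one phenotype
#'
#' Parents are Poisson in the window; offspring counts are Poisson with
#' mean `mean_offspring` and positions Gaussian around the parent with
#' spread `sigma`. The resulting intensity is
#' `parent_intensity * mean_offspring`. Other phenotypes may be added as
#' independent CSR backgrounds.
#'
#' @param phenotype Phenotype label for the clustered points.
#' @param parent_intensity Parent intensity (per um^2).
#' @param mean_offspring Mean offspring per parent.
#' @param sigma Cluster spread (um).
#' @param window A [tme_window()].
#' @param background Named intensities of additional CSR phenotypes.
#' @inheritParams simulate_csr
#' @return A `region_pattern`.
#' @export
simulate_clustered <- function(phenotype, parent_intensity, mean_offspring,
                               sigma, window, background = NULL,
                               seed = NULL, hierarchy = default_hierarchy(),
                               region_id = "sim", region_class = "tumor",
                               patient_id = "sim") {
  with_seed(seed, {
    np <- rpois(1, parent_intensity * window$area)
    pp <- .runif_window(np, window)
    off <- .thomas_offspring(pp$x, pp$y, mean_offspring, sigma, window)
    xs <- off$x; ys <- off$y; ph <- rep(phenotype, length(off$x))
    for (p in names(background)) {
      n <- rpois(1, background[[p]] * window$area)
      if (n > 0) {
        u <- .runif_window(n, window)
        xs <- c(xs, u$x); ys <- c(ys, u$y); ph <- c(ph, rep(p, n))
      }
    }
    .make_pattern(xs, ys, ph, window, hierarchy, region_id, region_class,
                  patient_id)
  })
}

#' Simulate a hard-core (inhibited) process for one phenotype
#'
#' Sequential dart throwing: uniform candidates are rejected while within
#' `hardcore_dist` of an accepted point. The target count is Poisson with
#' mean `intensity * area`; if the window saturates before reaching it the
#' pattern is returned with the points placed so far.
#'
#' @param phenotype Phenotype label.
#' @param intensity Target intensity (per um^2).
#' @param hardcore_dist Minimum inter-point distance (um).
#' @inheritParams simulate_clustered
#' @return A `region_pattern`.
#' @export
simulate_hardcore <- function(phenotype, intensity, hardcore_dist, window,
                              background = NULL, seed = NULL,
                              hierarchy = default_hierarchy(),
                              region_id = "sim", region_class = "tumor",
                              patient_id = "sim") {
  with_seed(seed, {
    n_target <- rpois(1, intensity * window$area)
    xs <- ys <- numeric(0)
    tries <- 0L; max_tries <- 200L * max(n_target, 1L)
    while (length(xs) < n_target && tries < max_tries) {
      tries <- tries + 1L
      u <- .runif_window(1, window)
      if (length(xs) == 0L ||
          min((u$x - xs)^2 + (u$y - ys)^2) >= hardcore_dist^2) {
        xs <- c(xs, u$x); ys <- c(ys, u$y)
      }
    }
    ph <- rep(phenotype, length(xs))
    for (p in names(background)) {
      n <- rpois(1, background[[p]] * window$area)
      if (n > 0) {
        b <- .runif_window(n, window)
        xs <- c(xs, b$x); ys <- c(ys, b$y); ph <- c(ph, rep(p, n))
      }
    }
    .make_pattern(xs, ys, ph, window, hierarchy, region_id, region_class,
                  patient_id)
  })
}

#' Simulate cross-type attraction or repulsion between two phenotypes
#'
#' Attraction: both phenotypes cluster around shared Poisson parents. Each
#' A point is a Thomas offspring of the parent set; each B point attaches
#' to a uniformly chosen A parent with probability `shared_fraction`
#' (Gaussian offset `sigma`), otherwise it is placed uniformly. With
#' `shared_fraction = 0` the two types are independent.
#'
#' Repulsion: A is CSR; B candidates are re-sampled until outside
#' `exclusion` of every A point (count preserving, so the two groups of a
#' matched-count cohort stay comparable); `preserve_intensity = FALSE`
#' thins instead. If less than 10% of the window is admissible the
#' remaining B points are placed uniformly.
#'
#' @param kind `"attraction"` or `"repulsion"`.
#' @param phenotypes Character 2-vector `c(A, B)`.
#' @param intensity Named intensities of A and B (per um^2).
#' @param shared_fraction Attraction: fraction of B points sharing A's
#'   parents (0..1).
#' @param sigma Attraction: Gaussian cluster spread (um).
#' @param parent_intensity Attraction: shared-parent intensity (per um^2).
#' @param exclusion Repulsion: exclusion distance (um).
#' @param preserve_intensity Repulsion: re-sample (default) or thin.
#' @inheritParams simulate_clustered
#' @return A `region_pattern`.
#' @export
simulate_cross_pair <- function(kind = c("attraction", "repulsion"),
                                phenotypes, intensity, window,
                                shared_fraction = 1, sigma = 15,
                                parent_intensity = NULL, exclusion = 25,
                                preserve_intensity = TRUE,
                                background = NULL, seed = NULL,
                                hierarchy = default_hierarchy(),
                                region_id = "sim", region_class = "tumor",
                                patient_id = "sim") {
  kind <- match.arg(kind)
  if (length(phenotypes) != 2L) stop_("phenotypes must name two labels")
  pa <- phenotypes[1]; pb <- phenotypes[2]
  la <- intensity[[pa]]; lb <- intensity[[pb]]
  if (is.null(la) || is.null(lb))
    stop_("intensity must be named for both phenotypes")
  with_seed(seed, {
    if (kind == "attraction") {
      kappa <- parent_intensity %||% (la / 5) # default 5 offspring/parent
      np <- max(rpois(1, kappa * window$area), 1L)
      pp <- .runif_window(np, window)
      off <- .thomas_offspring(pp$x, pp$y,
                               mean_offspring = la * window$area / np,
                               sigma = sigma, window = window)
      ax <- off$x; ay <- off$y
      nb <- rpois(1, lb * window$area)
      bx <- by <- numeric(nb)
      if (nb > 0) {
        shared <- runif(nb) < shared_fraction
        for (k in seq_len(nb)) {
          if (shared[k]) {
            par <- sample.int(np, 1L)
            repeat {
              cx <- pp$x[par] + rnorm(1, 0, sigma)
              cy <- pp$y[par] + rnorm(1, 0, sigma)
              if (cx >= window$xmin && cx <= window$xmax &&
                  cy >= window$ymin && cy <= window$ymax) break
            }
          } else {
            u <- .runif_window(1, window); cx <- u$x; cy <- u$y
          }
          bx[k] <- cx; by[k] <- cy
        }
      }
    } else {
      na <- rpois(1, la * window$area)
      ua <- .runif_window(na, window)
      ax <- ua$x; ay <- ua$y
      nb <- rpois(1, lb * window$area)
      bx <- by <- numeric(0)
      tries <- 0L; max_tries <- 200L * max(nb, 1L)
      while (length(bx) < nb && tries < max_tries) {
        tries <- tries + 1L
        u <- .runif_window(1, window)
        if (na == 0L ||
            min((u$x - ax)^2 + (u$y - ay)^2) >= exclusion^2) {
          bx <- c(bx, u$x); by <- c(by, u$y)
        }
      }
      if (!preserve_intensity) {
        # plain thinning: keep candidates drawn in the first nb attempts
        # (approximated by subsampling the accepted points at the
        # acceptance rate)
        rate <- length(bx) / max(tries, 1L)
        keep <- runif(length(bx)) < rate * nb / max(length(bx), 1L)
        bx <- bx[keep]; by <- by[keep]
      } else if (length(bx) < nb) {
        u <- .runif_window(nb - length(bx), window) # saturated window
        bx <- c(bx, u$x); by <- c(by, u$y)
      }
    }
    xs <- c(ax, bx); ys <- c(ay, by)
    ph <- c(rep(pa, length(ax)), rep(pb, length(bx)))
    for (p in names(background)) {
      n <- rpois(1, background[[p]] * window$area)
      if (n > 0) {
        u <- .runif_window(n, window)
        xs <- c(xs, u$x); ys <- c(ys, u$y); ph <- c(ph, rep(p, n))
      }
    }
    .make_pattern(xs, ys, ph, window, hierarchy, region_id, region_class,
                  patient_id)
  })
}

#' Simulate a two-group synthetic cohort with survival
#'
#' Patients are split into a control and an effect group. All regions
#' share per-phenotype intensities (so counts are uninformative by
#' construction); effect-group regions additionally carry cross-type
#' attraction between two phenotypes (default the T-cell and macrophage
#' representatives). Survival times are exponential with group-specific
#' hazards (control median `median_control` months, effect hazard
#' multiplied by `hazard_ratio`) with administrative censoring at
#' `followup_max` months.
#'
#' @param n_patients Total number of patients (>= 4); groups are balanced.
#' @param regions_per_patient Tumor regions per patient.
#' @param border_regions_per_patient Border regions per patient (same
#'   generative model), default 0.
#' @param window Shared region window.
#' @param intensity Named per-phenotype intensities (per um^2).
#' @param effect_phenotypes Character 2-vector: the attracted pair in the
#'   effect group.
#' @param shared_fraction,sigma Attraction parameters (see
#'   [simulate_cross_pair()]).
#' @param hazard_ratio Effect-group hazard multiplier (> 0).
#' @param median_control Control-group median survival (months).
#' @param followup_max Administrative censoring time (months).
#' @param seed Seed.
#' @param hierarchy Hierarchy used to mark cells.
#' @return Object of class `synthetic_cohort`: list with `patterns` (list
#'   of `region_pattern`), `survival` (data frame `patient_id`,
#'   `time_months`, `event`), `groups` (named character), and the effect
#'   description.
#' @export
simulate_cohort <- function(n_patients = 40, regions_per_patient = 3,
                            border_regions_per_patient = 0,
                            window = tme_window(0, 600, 0, 600),
                            intensity = c("PAX5+PD-L1-" = 4e-4,
                                          "CD3+CD8-PD-1-" = 2e-4,
                                          "CD163+PD-L1-" = 2e-4,
                                          "other" = 2e-4),
                            effect_phenotypes = c("CD3+CD8-PD-1-",
                                                  "CD163+PD-L1-"),
                            shared_fraction = 0.9, sigma = 15,
                            hazard_ratio = 3, median_control = 36,
                            followup_max = 60, seed = NULL,
                            hierarchy = default_hierarchy()) {
  if (n_patients < 4) stop_("need at least 4 patients")
  if (hazard_ratio <= 0) stop_("hazard_ratio must be > 0")
  n_ctrl <- floor(n_patients / 2)
  if (n_ctrl < 1 || n_patients - n_ctrl < 1)
    stop_("degenerate group sizes")
  groups <- setNames(rep(c("control", "effect"),
                         c(n_ctrl, n_patients - n_ctrl)),
                     sprintf("P%03d", seq_len(n_patients)))
  bg <- intensity[setdiff(names(intensity), effect_phenotypes)]
  h_ctrl <- log(2) / median_control
  with_seed(seed, {
    patterns <- list()
    for (pid in names(groups)) {
      n_reg <- regions_per_patient + border_regions_per_patient
      classes <- rep(c("tumor", "border"),
                     c(regions_per_patient, border_regions_per_patient))
      for (k in seq_len(n_reg)) {
        rid <- sprintf("%s_%s_%d", pid, classes[k], k)
        pat <- if (groups[[pid]] == "effect") {
          simulate_cross_pair("attraction", effect_phenotypes, intensity,
                              window, shared_fraction = shared_fraction,
                              sigma = sigma, background = bg,
                              hierarchy = hierarchy, region_id = rid,
                              region_class = classes[k], patient_id = pid)
        } else {
          simulate_csr(intensity, window, hierarchy = hierarchy,
                       region_id = rid, region_class = classes[k],
                       patient_id = pid)
        }
        patterns[[rid]] <- pat
      }
    }
    haz <- ifelse(groups == "effect", h_ctrl * hazard_ratio, h_ctrl)
    t_event <- rexp(n_patients, haz)
    event <- as.integer(t_event <= followup_max)
    time <- pmin(t_event, followup_max)
    surv <- data.frame(patient_id = names(groups), time_months = time,
                       event = event, stringsAsFactors = FALSE)
    structure(list(patterns = patterns, survival = surv, groups = groups,
                   effect = list(phenotypes = effect_phenotypes,
                                 shared_fraction = shared_fraction,
                                 sigma = sigma,
                                 hazard_ratio = hazard_ratio)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d regions, HR %.2g\n",
              length(x$groups), length(x$patterns),
              x$effect$hazard_ratio))
  invisible(x)
}

#' Write a synthetic cohort to disk as plain-text tables
#'
#' Emits one cell-table CSV per patient (the dialect
#' [parse_cell_table()] reads), a survival TSV and a ground-truth JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_patient <- split(cohort$patterns,
                      vapply(cohort$patterns, `[[`, "", "patient_id"))
  for (pid in names(by_patient)) {
    cells <- do.call(rbind, lapply(by_patient[[pid]], function(p)
      data.frame(x = p$x, y = p$y, phenotype = p$phenotype,
                 region_id = p$region_id, region_class = p$region_class,
                 patient_id = p$patient_id, stringsAsFactors = FALSE)))
    write_cell_table(cells, file.path(dir, paste0(pid, ".csv")))
  }
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(groups = as.list(cohort$groups), effect = cohort$effect),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
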