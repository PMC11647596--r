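#' Nested study design for a two-site urban thermal acclimation study
#'
#' Describes the factorial layout the rest of the package assumes: a set of
#' tree species sampled in two contrasting urban environments ("hot", i.e.
#' the urban heat island, and "cold"), a fixed number of trees per
#' species-site cell, a ladder of water-bath treatment temperatures for the
#' leaf-disk Fv/Fm assay, and the leaf-temperature grid used for
#' photosynthesis-temperature response curves.
#'
#' The lowest bath temperature is always the control treatment: disks at
#' that temperature define the undamaged Fv/Fm asymptote used for quality
#' control and for the damage-fraction thresholds.
#'
#' @param species Character vector of species codes. Defaults to the seven
#'   common street/park species ACPL, ACSA, CEOC, GLTR, QUMA, QURU, TICO.
#' @param sites Character vector of site labels, default `c("hot","cold")`.
#' @param trees_per_species_site Integer, trees sampled per species x site.
#' @param bath_temperatures_c Numeric, strictly increasing water-bath
#'   treatment temperatures in degrees C; the first (lowest) is the control.
#' @param disks_per_tree_per_temperature Integer, leaf disks per tree at
#'   each bath temperature.
#' @param at_curve_temperatures_c Numeric, leaf temperatures (degrees C) at
#'   which each photosynthesis-temperature curve is sampled.
#'
#' @return An object of class `study_design` (a list with the fields above
#'   plus `control_c`, the control bath temperature).
#' @examples
#' d <- study_design()
#' d$control_c              # 22
#' n_disks(d)               # 3780
#' n_trees(d)               # 140
#' @export
study_design <- function(species = c("ACPL", "ACSA", "CEOC", "GLTR",
                                     "QUMA", "QURU", "TICO"),
                         sites = c("hot", "cold"),
                         trees_per_species_site = 10,
                         bath_temperatures_c = c(22.0, 40.0, 42.2, 44.5,
                                                 47.0, 49.3, 51.5, 53.2, 56.5),
                         disks_per_tree_per_temperature = 3,
                         at_curve_temperatures_c = seq(20, 40, by = 2)) {
  stopifnot(length(species) >= 1, length(sites) >= 1,
            trees_per_species_site >= 1,
            disks_per_tree_per_temperature >= 1,
            length(bath_temperatures_c) >= 1,
            length(at_curve_temperatures_c) >= 1)
  if (anyDuplicated(species)) stop("duplicated species codes")
  if (any(diff(bath_temperatures_c) <= 0))
    stop("bath temperatures must be strictly increasing")
  if (!all(is.finite(bath_temperatures_c)) ||
      !all(is.finite(at_curve_temperatures_c)))
    stop("temperatures must be finite")
  out <- list(species = as.character(species),
              sites = as.character(sites),
              trees_per_species_site = as.integer(trees_per_species_site),
              bath_temperatures_c = as.numeric(bath_temperatures_c),
              disks_per_tree_per_temperature =
                as.integer(disks_per_tree_per_temperature),
              at_curve_temperatures_c = as.numeric(at_curve_temperatures_c),
              control_c = as.numeric(bath_temperatures_c[1]))
  class(out) <- "study_design"
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$species), "species x", length(x$sites),
      "sites x", x$trees_per_species_site, "trees\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  bath temperatures (C):",
      paste(x$bath_temperatures_c, collapse = ", "),
      "| control:", x$control_c, "\n")
  cat("  disks/tree/temperature:", x$disks_per_tree_per_temperature,
      "-> total disks:", n_disks(x), "\n")
  cat("  A-T curve grid (C):", paste(range(x$at_curve_temperatures_c),
                                     collapse = " to "),
      "in", length(x$at_curve_temperatures_c), "steps\n")
  invisible(x)
}

#' Design cell counts
#'
#' Closed-form record counts implied by a [study_design()]: total leaf disks
#' in the heat-tolerance assay and total trees sampled.
#'
#' @param design A `study_design`.
#' @return Integer count.
#' @export
n_disks <- function(design) {
  stopifnot(inherits(design, "study_design"))
  length(design$species) * length(design$sites) *
    design$trees_per_species_site * length(design$bath_temperatures_c) *
    design$disks_per_tree_per_temperature
}

#' @rdname n_disks
#' @export
n_trees <- function(design) {
  stopifnot(inherits(design, "study_design"))
  length(design$species) * length(design$sites) *
    design$trees_per_species_site
}
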