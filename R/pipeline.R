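#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything a reproducible run needs: the root seed (all
#' randomness derives from it), the study design, generator truth
#' parameters, the energy-balance vapor-path mode, the bootstrap
#' replication count, the Fv/Fm QC threshold and the day/night irradiance
#' threshold. `demo_run_config()` is a reduced design (3 species, 3 trees,
#' 30 bootstrap replicates, 10 days of microclimate) that completes in
#' well under a minute on one CPU.
#'
#' @param seed Root integer seed.
#' @param out_dir Output directory for all tables.
#' @param design A [study_design()].
#' @param n_days Days of microclimate to simulate.
#' @param n_boot Bootstrap replicates per tree (0 disables bootstrap CIs).
#' @param qc_threshold Minimum control-mean Fv/Fm, see [qc_filter()].
#' @param solar_threshold Day/night irradiance threshold, W m-2.
#' @param gwv_mode Energy-balance vapor-path mode.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("leafheat_run_"),
                       design = study_design(), n_days = 30, n_boot = 100,
                       qc_threshold = 0.75, solar_threshold = 5,
                       gwv_mode = "as_printed") {
  stopifnot(inherits(design, "study_design"), n_boot >= 0, n_days >= 1)
  out <- list(seed = as.integer(seed), out_dir = out_dir, design = design,
              n_days = n_days, n_boot = n_boot,
              qc_threshold = qc_threshold,
              solar_threshold = solar_threshold, gwv_mode = gwv_mode)
  class(out) <- "run_config"
  out
}

#' @rdname run_config
#' @export
demo_run_config <- function(seed = 1,
                            out_dir = tempfile("leafheat_demo_")) {
  run_config(seed = seed, out_dir = out_dir,
             design = study_design(species = c("ACSA", "QURU", "TICO"),
                                   trees_per_species_site = 3),
             n_days = 10, n_boot = 30)
}

write_table <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# leafheat v%s seed=%d",
                     as.character(utils::packageVersion("leafheat")), seed),
             con)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE,
                          justify = "none"),
                   con, row.names = FALSE, quote = FALSE)
}

#' Read a pipeline CSV table
#'
#' Reads tables written by [run_pipeline()] (a `#`-prefixed provenance
#' header followed by a standard CSV).
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage end to end: simulate the study (microclimate,
#' disks, gas exchange, traits), contrast the two sites' temperature
#' regimes, compute leaf traits, predict leaf temperatures with the energy
#' balance, fit the photosynthesis-temperature responses and contrast
#' their parameters, fit the heat-tolerance curves (with bootstrap CIs for
#' each tree when `n_boot > 0`) and build the species table. Each stage's
#' output is written as a CSV under `config$out_dir` with a provenance
#' header carrying the seed; re-running the same config reproduces every
#' file byte for byte. A stage failure aborts with a stage-tagged message
#' and leaves a `.partial` marker.
#'
#' Effective leaf width for the energy balance is proxied by the
#' equal-area circle diameter of each tree's mean leaf area (silhouette
#' masks are not part of the simulated tables); real analyses should
#' supply widths measured with [effective_leaf_width()].
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage outputs (`microclimate_contrast`,
#'   `tree_traits`, `energy_balance`, `tr_fits`, `tr_contrast`, `ht_fits`,
#'   `ht_species`, `ht_ci`, `files`).
#' @examples
#' \donttest{
#' res <- run_pipeline(demo_run_config(seed = 7))
#' res$ht_species
#' }
#' @export
run_pipeline <- function(config = demo_run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  partial <- file.path(config$out_dir, "RUN.partial")
  file.create(partial)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed
  design <- config$design
  files <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_table(df, path, seed)
    files[[name]] <<- path
  }

  mc <- stage("simulate", sim_microclimate(n_days = config$n_days,
                                           seed = sub_seed(seed, 1)))
  disks <- stage("simulate", sim_fvfm_disks(design,
                                            seed = sub_seed(seed, 2)))
  gas <- stage("simulate", sim_at_curves(design, seed = sub_seed(seed, 3)))
  traits <- stage("simulate", sim_trait_table(design,
                                              seed = sub_seed(seed, 4)))
  emit(mc, "microclimate.csv"); emit(disks, "disks.csv")
  emit(gas, "gas_exchange.csv"); emit(traits, "traits.csv")

  contrast <- stage("microclimate", site_contrast(
    mc[mc$site == "hot", ], mc[mc$site == "cold", ],
    solar_threshold = config$solar_threshold))
  emit(contrast, "site_contrast.csv")

  tree_traits <- stage("traits", tree_trait_means(traits))
  emit(tree_traits, "tree_traits.csv")

  eb_in <- stage("energy_balance", {
    gs_tree <- stats::aggregate(gs ~ species + site + tree, data = gas,
                                FUN = mean)
    tt <- merge(tree_traits, gs_tree, by = c("species", "site", "tree"),
                all.x = TRUE)
    tt$gs[is.na(tt$gs)] <- mean(gs_tree$gs)
    env <- do.call(rbind, lapply(split(mc, mc$site), function(m) {
      day <- m$solar_wm2 > config$solar_threshold
      data.frame(site = m$site[1], tair_c = mean(m$tair_c[day]),
                 solar_wm2 = mean(m$solar_wm2[day]),
                 stringsAsFactors = FALSE)
    }))
    tt <- merge(tt, env, by = "site")
    data.frame(species = tt$species, site = tt$site, tree = tt$tree,
               tair_c = tt$tair_c, rh_pct = 55, wind_ms = 1,
               solar_wm2 = tt$solar_wm2,
               width_m = 2 * sqrt(tt$area_mm2 / pi) / 1000,
               gs_mol = tt$gs, absorptance = tt$absorptance,
               stringsAsFactors = FALSE)
  })
  eb <- stage("energy_balance", batch_delta_t(eb_in,
                                              gwv_mode = config$gwv_mode))
  emit(eb$results, "energy_balance.csv")
  emit(eb$slopes, "energy_balance_slopes.csv")

  tr_fits <- stage("fit_topt", fit_temperature_response_all(gas))
  emit(tr_fits, "tr_fits.csv")
  tr_contrast <- stage("fit_topt",
                       site_parameter_contrast(tr_fits,
                                               sites = design$sites[1:2]))
  emit(tr_contrast, "tr_contrast.csv")

  ht_fits <- stage("fit_ht", fit_heat_tolerance_all(
    disks, min_control_fvfm = config$qc_threshold))
  emit(ht_fits, "ht_fits.csv")
  ht_species <- stage("fit_ht",
                      species_ht_table(ht_fits, sites = design$sites[1:2]))
  emit(ht_species, "ht_species.csv")

  ht_ci <- NULL
  if (config$n_boot > 0) {
    ht_ci <- stage("fit_ht", {
      key <- interaction(disks$species, disks$site, disks$tree, drop = TRUE)
      rows <- lapply(seq_along(levels(key)), function(i) {
        g <- disks[key == levels(key)[i], ]
        bt <- tryCatch(bootstrap_thresholds(g$bath_c, g$fvfm,
                                            n_boot = config$n_boot,
                                            seed = sub_seed(seed, 100 + i)),
                       error = function(e) NULL)
        if (is.null(bt)) return(NULL)
        cbind(data.frame(species = g$species[1], site = g$site[1],
                         tree = g$tree[1], stringsAsFactors = FALSE),
              bt$table)
      })
      do.call(rbind, rows)
    })
    emit(ht_ci, "ht_bootstrap_ci.csv")
  }

  report <- data.frame(
    item = c("seed", "species", "sites", "trees", "disks",
             "qc_trees_removed", "tr_fits_converged", "ht_fits_converged"),
    value = c(seed, length(design$species), length(design$sites),
              n_trees(design), nrow(disks),
              n_trees(design) - length(unique(interaction(
                ht_fits$species, ht_fits$site, ht_fits$tree))),
              sum(tr_fits$converged), sum(ht_fits$converged)))
  emit(report, "report.csv")
  unlink(partial)
  invisible(list(microclimate_contrast = contrast,
                 tree_traits = tree_traits, energy_balance = eb,
                 tr_fits = tr_fits, tr_contrast = tr_contrast,
                 ht_fits = ht_fits, ht_species = ht_species, ht_ci = ht_ci,
                 files = files))
}

#' Validate pipeline CSV tables against their schemas
#'
#' Checks column presence and row-level invariants for the four input
#' table types: `microclimate` (finite temperatures, non-negative
#' irradiance, increasing timestamps), `disks` (fm > f0 > 0, Fv/Fm in
#' [0, 1]), `gas` (finite leaf temperatures in [10, 50], positive gs and
#' E) and `traits` (positive masses with fresh >= dry, reflectance +
#' transmittance < 1).
#'
#' @param paths Named character vector or list: names are table types
#'   (`microclimate`, `disks`, `gas`, `traits`), values are file paths.
#' @return Data.frame of violations (`file`, `row`, `column`, `problem`);
#'   zero rows when everything checks out.
#' @export
validate_tables <- function(paths) {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  schemas <- list(
    microclimate = c("site", "timestamp", "tair_c", "solar_wm2"),
    disks = c("species", "site", "tree", "disk", "bath_c", "f0", "fm",
              "fvfm"),
    gas = c("species", "site", "tree", "leaf", "tleaf_c", "anet", "gs",
            "e"),
    traits = c("species", "site", "tree", "leaf", "area_mm2",
               "thickness_mm", "fresh_mg", "dry_mg", "reflectance",
               "transmittance"))
  probs <- list()
  note <- function(file, row, column, problem)
    probs[[length(probs) + 1]] <<- data.frame(
      file = file, row = row, column = column, problem = problem,
      stringsAsFactors = FALSE)
  flag <- function(file, bad, column, problem)
    for (r in which(bad)) note(file, r, column, problem)

  for (type in names(paths)) {
    path <- paths[[type]]
    if (!type %in% names(schemas)) {
      note(path, NA, NA, paste("unknown table type:", type)); next
    }
    if (!file.exists(path)) {
      note(path, NA, NA, "file not found"); next
    }
    d <- tryCatch(read_table(path), error = function(e) NULL)
    if (is.null(d)) { note(path, NA, NA, "unreadable file"); next }
    miss <- setdiff(schemas[[type]], names(d))
    if (length(miss)) {
      note(path, NA, paste(miss, collapse = ","), "missing columns"); next
    }
    switch(type,
      microclimate = {
        flag(path, !is.finite(d$tair_c), "tair_c", "non-finite")
        flag(path, d$solar_wm2 < 0, "solar_wm2", "negative irradiance")
      },
      disks = {
        flag(path, d$fvfm < 0 | d$fvfm > 1, "fvfm", "outside [0, 1]")
        flag(path, d$f0 <= 0, "f0", "non-positive")
        flag(path, d$fm <= d$f0, "fm", "fm <= f0")
      },
      gas = {
        flag(path, d$tleaf_c < 10 | d$tleaf_c > 50, "tleaf_c",
             "outside [10, 50]")
        flag(path, d$gs <= 0, "gs", "non-positive")
        flag(path, d$e <= 0, "e", "non-positive")
      },
      traits = {
        flag(path, d$area_mm2 <= 0, "area_mm2", "non-positive")
        flag(path, d$dry_mg > d$fresh_mg, "dry_mg", "dry > fresh")
        flag(path, d$reflectance + d$transmittance >= 1, "reflectance",
             "reflectance + transmittance >= 1")
      })
  }
  if (length(probs) == 0)
    return(data.frame(file = character(), row = integer(),
                      column = character(), problem = character()))
  out <- do.call(rbind, probs)
  rownames(out) <- NULL
  out
}
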