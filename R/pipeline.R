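# End-to-end orchestration: climate novelty -> exposure -> trait scoring ->
# vulnerability categories -> surveillance representation, from a single
# configuration, with run metadata; plus the fixture-only audit that pushes
# the packaged reference table through the category machinery.

#' Run the full vulnerability-assessment pipeline
#'
#' Executes the stages in order on synthetic inputs generated from `config`
#' (or on externally supplied tables): climate novelty mapping, species
#' exposure, trait scoring, eight-way categorization, and the surveillance
#' audit. Identical configuration and seed produce identical result bundles.
#'
#' @param config a [synthetic_config()] object.
#' @param inputs optional named list overriding generated inputs: `climate`,
#'   `occurrences`, `traits`, `surveillance` data.frames in the interchange
#'   layouts documented on the respective generators.
#' @param tercile_method_climate,tercile_method_traits tercile method per
#'   stage (`"quantile"` or `"range_thirds"`).
#' @param exposure_rule,exposure_cutoff passed to [species_exposure()].
#' @param sed_sqrt passed to [compute_sed()].
#' @param out_dir optional directory; when given, every stage table is
#'   written there as CSV along with `run_metadata.yaml`.
#' @return list of class `"tva_run"`: `sed`, `exposure`, `trait_scores`,
#'   `vulnerability` (assignments + tally), `surveillance` (included,
#'   excluded, representation), `metadata`.
#' @export
run_pipeline <- function(config,
                         inputs = list(),
                         tercile_method_climate = "quantile",
                         tercile_method_traits = "quantile",
                         exposure_rule = "cutoff",
                         exposure_cutoff = 0.5,
                         sed_sqrt = FALSE,
                         out_dir = NULL) {
  validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }

  climate <- stage("climate", inputs$climate %||% generate_climate(config))
  sed <- stage("climate", climate_novelty(climate, config$baseline_years,
                                          config$recent_years,
                                          tercile_method = tercile_method_climate,
                                          sed_sqrt = sed_sqrt))
  occurrences <- stage("exposure",
                       inputs$occurrences %||% generate_occurrences(config))
  exposure <- stage("exposure",
                    species_exposure(occurrences, sed, rule = exposure_rule,
                                     cutoff = exposure_cutoff))
  traits <- stage("traits", inputs$traits %||% generate_traits(config))
  scores <- stage("traits",
                  score_traits(traits, tercile_method = tercile_method_traits))

  flags <- stage("vulnerability", {
    idx <- match(scores$species, exposure$species)
    if (anyNA(idx)) {
      stop(sprintf("species '%s' has no exposure score",
                   scores$species[is.na(idx)][1]), call. = FALSE)
    }
    data.frame(species = scores$species,
               exposed = exposure$high_exposure[idx],
               sensitive = scores$high_sensitivity,
               low_ac = scores$low_adaptive_capacity)
  })
  vulnerability <- stage("vulnerability", categorize_all(flags))

  surveillance <- stage("surveillance",
                        inputs$surveillance %||%
                          generate_surveillance(config, traits))
  filtered <- stage("surveillance",
                    filter_records(surveillance,
                                   window = c(config$surveillance$date_start,
                                              config$surveillance$date_end)))
  representation <- stage("surveillance",
                          representation_summary(filtered$included,
                                                 vulnerability$assignments,
                                                 traits[c("species", "order")]))

  metadata <- list(seed = config$seed,
                   grid = c(config$grid_rows, config$grid_cols),
                   baseline_years = range(config$baseline_years),
                   recent_years = range(config$recent_years),
                   tercile_method_climate = tercile_method_climate,
                   tercile_method_traits = tercile_method_traits,
                   sed_sqrt = sed_sqrt,
                   exposure_rule = exposure_rule,
                   exposure_cutoff = exposure_cutoff,
                   sed_breaks = as.numeric(attr(sed, "breaks")),
                   n_species = config$n_species,
                   package_version =
                     as.character(utils::packageVersion("climvuln")))

  run <- structure(list(sed = sed, exposure = exposure,
                        trait_scores = scores,
                        vulnerability = vulnerability,
                        surveillance = c(filtered,
                                         list(representation = representation)),
                        metadata = metadata),
                   class = "tva_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(run$sed, "sed")
  wr(run$exposure, "exposure")
  wr(run$trait_scores, "trait_scores")
  wr(run$vulnerability$assignments, "vulnerability")
  wr(run$vulnerability$tally, "category_tally")
  wr(run$surveillance$included, "surveillance_included")
  wr(run$surveillance$excluded, "surveillance_excluded")
  wr(run$surveillance$representation$per_order, "records_per_order")
  wr(run$surveillance$representation$per_category_records,
     "records_per_category")
  yaml::write_yaml(run$metadata, file.path(out_dir, "run_metadata.yaml"))
  invisible(out_dir)
}

#' @export
print.tva_run <- function(x, ...) {
  cat("Trait-based vulnerability assessment run\n")
  cat(sprintf("  %d cells, SED mean %.3f (breaks %.3f / %.3f)\n",
              nrow(x$sed), mean(x$sed$sed), x$metadata$sed_breaks[1],
              x$metadata$sed_breaks[2]))
  cat(sprintf("  %d species: %d exposed, %d sensitive, %d low adaptive capacity\n",
              nrow(x$exposure), sum(x$exposure$high_exposure),
              sum(x$trait_scores$high_sensitivity),
              sum(x$trait_scores$low_adaptive_capacity)))
  cat("  category tally:\n")
  print(x$vulnerability$tally, row.names = FALSE)
  invisible(x)
}

#' Audit the packaged species-to-category table
#'
#' Loads the packaged reference assignment of 59 species to vulnerability
#' categories, inverts each category into its (exposed, sensitive, low
#' adaptive capacity) flags, re-tallies the categories, and cross-tabulates
#' each dimension flag per taxonomic order. Optionally joins a surveillance
#' record table to summarize how the categories are represented in the
#' submissions.
#'
#' @param surveillance optional data.frame of surveillance records (see
#'   [filter_records()] for the layout); when supplied, records are filtered
#'   and cross-tabulated against the reference categories.
#' @param window date window for surveillance filtering.
#' @return list of class `"tva_fixture_audit"`: `assignments` (species,
#'   order, flags, category, label), `tally`, `headline` (named counts:
#'   `n_species`, `n_exposed`, `n_sensitive`, `n_low_ac`, and the matching
#'   percentages), `by_order` (per-order species totals and flag counts),
#'   and, when surveillance was given, `representation`.
#' @export
#' @examples
#' audit <- fixture_audit()
#' audit$headline["n_exposed"]  # 15
fixture_audit <- function(surveillance = NULL,
                          window = c("2008-01-01", "2022-08-31")) {
  fx <- load_reference_categories()
  flags <- invert_category(fx$category)
  assignments <- data.frame(species = fx$species, order = fx$order,
                            exposed = flags$exposed,
                            sensitive = flags$sensitive,
                            low_ac = flags$low_ac,
                            category = fx$category,
                            label = category_labels[fx$category])
  tally <- categorize_all(assignments)$tally

  n <- nrow(assignments)
  headline <- c(n_species = n,
                n_exposed = sum(assignments$exposed),
                n_sensitive = sum(assignments$sensitive),
                n_low_ac = sum(assignments$low_ac),
                pct_exposed = 100 * sum(assignments$exposed) / n,
                pct_sensitive = 100 * sum(assignments$sensitive) / n,
                pct_low_ac = 100 * sum(assignments$low_ac) / n)

  agg <- function(flag) {
    tapply(assignments[[flag]], assignments$order, sum)
  }
  orders <- sort(unique(assignments$order))
  by_order <- data.frame(order = orders,
                         n_species = as.vector(table(assignments$order)[orders]),
                         n_exposed = as.vector(agg("exposed")[orders]),
                         n_sensitive = as.vector(agg("sensitive")[orders]),
                         n_low_ac = as.vector(agg("low_ac")[orders]))

  out <- list(assignments = assignments, tally = tally,
              headline = headline, by_order = by_order)
  if (!is.null(surveillance)) {
    filtered <- filter_records(surveillance, window = window)
    out$representation <- representation_summary(
      filtered$included, assignments, assignments[c("species", "order")])
  }
  structure(out, class = "tva_fixture_audit")
}

#' @export
print.tva_fixture_audit <- function(x, ...) {
  h <- x$headline
  cat("Vulnerability audit of the packaged species table\n")
  cat(sprintf("  %d species: %d exposed (%.1f%%), %d sensitive (%.1f%%), %d low adaptive capacity (%.1f%%)\n",
              h["n_species"], h["n_exposed"], h["pct_exposed"],
              h["n_sensitive"], h["pct_sensitive"], h["n_low_ac"],
              h["pct_low_ac"]))
  cat("  category tally:\n")
  print(x$tally, row.names = FALSE)
  cat("  per-order flag counts:\n")
  print(x$by_order, row.names = FALSE)
  invisible(x)
}
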