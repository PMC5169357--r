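#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline]: either a directory with a
#' previously written bundle or generator parameters (exactly one of the
#' two), plus the combination rules and output options.
#'
#' @param bundle_dir Directory holding a bundle written by
#'   [write_bundle], or `NULL` to generate.
#' @param params [landscape_params] used when `bundle_dir` is `NULL`.
#' @param cost_rule `"mean"` or `"max"` aggregation of the cost layers.
#' @param benefit_mode `"production"` or `"population"`.
#' @param n_bins Bins per axis of the bivariate classification.
#' @param buffer_width_km Road-buffer half-width (km).
#' @param sensitivity Run the three sensitivity substitutions.
#' @param threshold Changed-cell threshold for sensitivity summaries.
#' @param out_dir Output directory, or `NULL` for no files.
#' @return Object of class `rs_pipeline_config`.
#' @export
pipeline_config <- function(bundle_dir = NULL, params = NULL,
                            cost_rule = c("mean", "max"),
                            benefit_mode = c("production", "population"),
                            n_bins = 10, buffer_width_km = 10,
                            sensitivity = TRUE, threshold = 0.2,
                            out_dir = NULL) {
  cost_rule <- match.arg(cost_rule)
  benefit_mode <- match.arg(benefit_mode)
  if (is.null(bundle_dir) == is.null(params))
    stop("config error: give exactly one of bundle_dir or params")
  if (!is.null(bundle_dir) && !file.exists(file.path(bundle_dir,
                                                     "manifest.yml")))
    stop("config error: no bundle manifest in ", bundle_dir)
  if (!is.null(params) && !inherits(params, "rs_landscape_params"))
    stop("config error: params must come from landscape_params()")
  if (n_bins < 2) stop("config error: n_bins must be >= 2")
  if (buffer_width_km <= 0) stop("config error: buffer_width_km must be > 0")
  if (threshold <= 0 || threshold >= 1)
    stop("config error: threshold must be in (0, 1)")
  structure(list(bundle_dir = bundle_dir, params = params,
                 cost_rule = cost_rule, benefit_mode = benefit_mode,
                 n_bins = as.integer(n_bins),
                 buffer_width_km = buffer_width_km,
                 sensitivity = isTRUE(sensitivity), threshold = threshold,
                 out_dir = out_dir),
            class = "rs_pipeline_config")
}

# benefit + cost aggregates for a bundle under given rules
compute_surfaces <- function(bundle, cost_rule = "mean",
                             benefit_mode = "production",
                             crops = bundle$crops) {
  areas <- cell_areas(bundle$grid)
  prod_gap <- production_gap(crops, bundle$grid)
  benefit <- if (benefit_mode == "population")
    population_benefit(bundle$population, bundle$travel_time)
  else benefit_surface(prod_gap, bundle$travel_time)
  vert <- vertebrate_importance(bundle$species_ranges, bundle$natural_cover,
                                areas)
  carbon <- carbon_cost(bundle$carbon_biomass, bundle$carbon_soil30,
                        bundle$natural_cover, areas)
  climate <- climate_cost(bundle$ecoregion_id, bundle$ecoregion_indices,
                          bundle$natural_cover)
  cost <- aggregate_cost(list(vertebrates = vert, carbon = carbon,
                              climate = climate), rule = cost_rule)
  list(prod_gap = prod_gap, benefit = benefit, cost = cost,
       components = list(vertebrates = vert, carbon = carbon,
                         climate = climate),
       areas = areas)
}

#' Run the full screening pipeline
#'
#' Loads or generates the landscape, builds the aggregate benefit and
#' cost surfaces, intersects them into the bivariate classification,
#' runs the three sensitivity substitutions (alternative yield-gap data,
#' max instead of mean cost rule, population instead of production
#' benefit), builds the existing-road density surface, and summarises
#' every road proposal over its buffer. If `out_dir` is set, all
#' artifacts are written (rasters as ASCII grids, tables as CSV) along
#' with a run manifest; outputs are byte-identical across reruns of the
#' same configuration.
#'
#' @param config [pipeline_config].
#' @return Object of class `roadscape_run`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rs_pipeline_config"))
  stage <- "load inputs"
  result <- tryCatch({
    bundle <- if (!is.null(config$bundle_dir)) read_bundle(config$bundle_dir)
              else generate_landscape(config$params)

    stage <- "aggregate surfaces"
    main <- compute_surfaces(bundle, config$cost_rule, config$benefit_mode)

    stage <- "bivariate intersection"
    biv <- bivariate_classify(main$benefit, main$cost, config$n_bins)

    sens <- NULL
    if (config$sensitivity) {
      stage <- "sensitivity analyses"
      alt_benefit <- benefit_surface(
        production_gap(bundle$crops_alt, bundle$grid), bundle$travel_time)
      max_cost <- aggregate_cost(main$components, rule = "max")
      pop_benefit <- population_benefit(bundle$population,
                                        bundle$travel_time)
      diffs <- list(
        alt_yieldgap = difference_map(alt_benefit, main$benefit,
                                      "alternative yield-gap data"),
        max_cost_rule = difference_map(max_cost, main$cost,
                                       "max instead of mean cost rule"),
        population_benefit = difference_map(pop_benefit, main$benefit,
                                            "population-based benefit"))
      sens <- list(
        diffs = diffs,
        changed = vapply(diffs, changed_fraction,
                         numeric(1), threshold = config$threshold),
        surfaces = list(alt_yieldgap = alt_benefit,
                        max_cost_rule = max_cost,
                        population_benefit = pop_benefit))
    }

    stage <- "road assessment"
    density <- road_density(bundle$roads_existing, bundle$grid, main$areas)
    summary_surfaces <- list(benefit = main$benefit, cost = main$cost,
                             travel_time = bundle$travel_time,
                             population = bundle$population,
                             road_density = density)
    road_summaries <- do.call(rbind, lapply(
      bundle$road_proposals, road_summary, surfaces = summary_surfaces,
      grid = bundle$grid, width_km = config$buffer_width_km))
    road_profiles <- do.call(rbind, lapply(
      bundle$road_proposals, road_profile, benefit = main$benefit,
      cost = main$cost, grid = bundle$grid))

    structure(list(config = config, bundle = bundle,
                   prod_gap = main$prod_gap, benefit = main$benefit,
                   cost = main$cost, cost_components = main$components,
                   bivariate = biv, sensitivity = sens,
                   road_density = density, road_summaries = road_summaries,
                   road_profiles = road_profiles),
              class = "roadscape_run")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) write_run(result, config$out_dir)
  result
}

# write all pipeline artifacts; deterministic (no timestamps)
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(s, name) {
    write_surface(s, file.path(out_dir, paste0(name, ".asc")))
    files <<- c(files, paste0(name, ".asc"))
  }
  put(run$prod_gap, "production_gap")
  put(run$benefit, "benefit")
  put(run$cost, "cost")
  g <- run$bundle$grid
  put(rs_surface(g, run$bivariate$benefit_bin * run$bivariate$n_bins +
                   run$bivariate$cost_bin, "benefit_bin*n_bins+cost_bin"),
      "bivariate_class")
  put(run$road_density, "road_density")
  qc <- as.data.frame(run$bivariate$quadrant_counts)
  names(qc) <- c("quadrant", "n_cells")
  utils::write.csv(qc, file.path(out_dir, "quadrant_counts.csv"),
                   row.names = FALSE)
  files <- c(files, "quadrant_counts.csv")
  if (!is.null(run$sensitivity)) {
    for (nm in names(run$sensitivity$diffs)) {
      d <- run$sensitivity$diffs[[nm]]
      put(rs_surface(g, d$delta, "delta (new - original)"),
          paste0("diff_", nm))
    }
    cf <- data.frame(substitution = names(run$sensitivity$changed),
                     threshold = run$config$threshold,
                     changed_fraction = unname(run$sensitivity$changed))
    utils::write.csv(cf, file.path(out_dir, "changed_fractions.csv"),
                     row.names = FALSE)
    files <- c(files, "changed_fractions.csv")
  }
  utils::write.csv(run$road_summaries,
                   file.path(out_dir, "road_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(run$road_profiles,
                   file.path(out_dir, "road_profiles.csv"),
                   row.names = FALSE)
  files <- c(files, "road_summaries.csv", "road_profiles.csv")
  cfg <- run$config
  yaml::write_yaml(list(
    config = list(cost_rule = cfg$cost_rule, benefit_mode = cfg$benefit_mode,
                  n_bins = cfg$n_bins, buffer_width_km = cfg$buffer_width_km,
                  sensitivity = cfg$sensitivity, threshold = cfg$threshold,
                  seed = if (!is.null(cfg$params)) cfg$params$seed),
    package_version = as.character(utils::packageVersion("roadscape")),
    n_valid_cells = sum(g$valid_mask),
    files = files),
    file.path(out_dir, "run_manifest.yml"), precision = 15)
  invisible(files)
}

#' @export
print.roadscape_run <- function(x, ...) {
  g <- x$bundle$grid
  cat(sprintf("<roadscape_run> %d x %d grid (%d valid cells)\n",
              g$n_rows, g$n_cols, sum(g$valid_mask)))
  cat(sprintf("  benefit: %s mode; cost: %s rule; %d x %d bins\n",
              x$config$benefit_mode, x$config$cost_rule,
              x$bivariate$n_bins, x$bivariate$n_bins))
  r <- stats::cor(as.vector(x$benefit$values), as.vector(x$cost$values),
                  use = "complete.obs")
  cat(sprintf("  benefit-cost Pearson r = %.3f\n", r))
  invisible(x)
}

#' @export
summary.roadscape_run <- function(object, ...) {
  x <- object
  cat("Benefit-cost screening summary\n")
  cat("------------------------------\n")
  pg <- x$prod_gap$values
  cat(sprintf("Total closable production gap: %.4g GJ/y over %d cells\n",
              sum(pg, na.rm = TRUE), sum(!is.na(pg))))
  cat("\nQuadrant shares (0.5 split of the 0-1 scales):\n")
  qc <- x$bivariate$quadrant_counts
  for (nm in names(qc))
    cat(sprintf("  %-26s %6d (%.1f%%)\n", nm, qc[[nm]],
                100 * qc[[nm]] / sum(qc)))
  if (!is.null(x$sensitivity)) {
    cat(sprintf("\nCells changed by >|%.2g| under each substitution:\n",
                x$config$threshold))
    for (nm in names(x$sensitivity$changed))
      cat(sprintf("  %-22s %.1f%%\n", nm,
                  100 * x$sensitivity$changed[[nm]]))
  }
  cat(sprintf("\nRoad proposals assessed: %d (buffer %.0f km)\n",
              nrow(x$road_summaries), x$config$buffer_width_km))
  best <- x$road_summaries[order(x$road_summaries$mean_cost), ]
  cat("  lowest mean cost:",
      paste(utils::head(best$road_id, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a pipeline run
#'
#' Four-panel overview: benefit surface, cost surface, bivariate
#' quadrants, and sensitivity changed fractions.
#'
#' @param x `roadscape_run`.
#' @param ... Unused.
#' @export
plot.roadscape_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  img <- function(m, main, col) {
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                    main = main, col = col, useRaster = TRUE)
  }
  img(x$benefit$values, "potential benefit",
      grDevices::hcl.colors(10, "YlGn", rev = TRUE))
  img(x$cost$values, "potential cost",
      grDevices::hcl.colors(10, "PuRd", rev = TRUE))
  quad_num <- matrix(match(x$bivariate$quadrant, QUADRANT_LEVELS),
                     nrow(x$bivariate$quadrant))
  img(quad_num, "quadrants",
      c("#6b8e23", "#e8e4d8", "#7b3294", "#2d2d2d"))
  if (!is.null(x$sensitivity)) {
    graphics::barplot(x$sensitivity$changed, las = 2, cex.names = 0.7,
                      main = sprintf("changed > |%.2g|", x$config$threshold),
                      ylim = c(0, 1))
  } else graphics::plot.new()
  invisible(x)
}
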