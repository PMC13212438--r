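## End-to-end orchestration: simulate/load -> thin -> background ->
## screen -> tune -> final fit -> project -> MESS -> classify ->
## dynamics -> risk, with per-stage seeds derived from one master seed
## (seed * 100 + stage counter) and a JSON run manifest.

#' Read and validate a run configuration
#'
#' A single declarative YAML file; see the package vignette for the
#' schema. Unknown top-level keys are rejected.
#'
#' @param path YAML config file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "species", "simulate", "occurrences", "layers",
             "scenarios", "thin_km", "background", "replicates",
             "feature_knots", "max_iter", "tol", "tune", "breaks",
             "densities", "out")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$thin_km <- cfg$thin_km %||% 1
  cfg$background <- cfg$background %||% 10000L
  cfg$replicates <- cfg$replicates %||% 10L
  cfg$feature_knots <- cfg$feature_knots %||% 50L
  cfg$max_iter <- cfg$max_iter %||% 1000L
  cfg$tol <- cfg$tol %||% 1e-5
  cfg$breaks <- cfg$breaks %||% "equal"
  cfg$tune <- utils::modifyList(
    list(generations = 40L, pop_size = 92L, exhaustive = FALSE,
         rm_indices = 0:25, fc_indices = 0:4), cfg$tune %||% list())
  if (is.null(cfg$simulate) && (is.null(cfg$occurrences) || is.null(cfg$layers)))
    stop("config needs either a 'simulate' block or occurrences + layers")
  cfg
}

buildSimSpec <- function(sim, seed) {
  vars <- lapply(sim$variables, function(v) v)
  landscapeSpec(n_rows = sim$n_rows, n_cols = sim$n_cols,
                variables = vars,
                origin_lon = sim$origin_lon %||% 100,
                origin_lat = sim$origin_lat %||% 45,
                cell_size = sim$cell_size %||% 0.1,
                nodata_fraction = sim$nodata_fraction %||% 0,
                seed = seed)
}

#' Run the full modelling pipeline
#'
#' Deterministic given the config (all randomness flows from
#' \code{config$seed} through per-stage derived seeds). Outputs land in
#' \code{config$out}: occurrence CSVs, the archive and model JSON,
#' suitability / MESS / class / change rasters (ASCII grid), area and
#' centroid CSVs, per-species risk outputs, and \code{manifest.json}.
#'
#' @param config list from \code{\link{readRunConfig}}, or a path to the
#'   YAML file.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$out %||% "enmopt_run"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), outputs = character())
  note <- function(stage, ok, ...) {
    manifest$stages[[stage]] <<- c(list(ok = ok), list(...))
  }
  emit <- function(path) manifest$outputs <<- c(manifest$outputs, path)
  seed_for <- function(i) config$seed * 100L + i

  ## 1. simulate or load --------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    spec <- buildSimSpec(sim, seed_for(1L))
    stack <- generateStack(spec)
    truth <- sim$truth
    occ <- samplePresences(stack, unlist(truth$coefficients),
                           truth$n_presences,
                           quad_coefficients = unlist(truth$quad_coefficients),
                           seed = seed_for(2L),
                           species = config$species %||% "synthetic")
    scen_stacks <- list(current = stack)
    for (nm in names(config$scenarios %||% list())) {
      sc <- config$scenarios[[nm]]
      scen_stacks[[nm]] <- perturbStack(stack, add = unlist(sc$add),
                                        mul = unlist(sc$mul))
    }
    densities <- lapply(config$densities %||% list(), function(d)
      generateDensity(spec, zero_fraction = d$zero_fraction %||% 0.3,
                      seed = seed_for(3L) + (d$seed_offset %||% 0L),
                      meanlog = d$meanlog %||% 2, sdlog = d$sdlog %||% 1))
    note("simulate", TRUE, n_presences = nrow(occ),
         grid = paste(gridDim(stack), collapse = "x"))
  } else {
    occ <- readOccurrences(config$occurrences)
    scen_stacks <- lapply(config$layers, function(paths) readStack(unlist(paths)))
    if (is.null(scen_stacks$current)) stop("layers must include a 'current' entry")
    stack <- scen_stacks$current
    densities <- lapply(config$densities %||% list(), function(d)
      readAsciiGrid(d)$values)
    note("simulate", TRUE, mode = "loaded", n_presences = nrow(occ))
  }
  writeOccurrences(occ, file.path(out, "occurrences_raw.csv")); emit("occurrences_raw.csv")

  ## 2. thin --------------------------------------------------------------
  occ_t <- thinOccurrences(occ, thin_km = config$thin_km, seed = seed_for(4L))
  writeOccurrences(occ_t, file.path(out, "occurrences_thinned.csv"))
  emit("occurrences_thinned.csv")
  note("thin", TRUE, n_before = nrow(occ), n_after = nrow(occ_t))

  ## presence cells and values
  tr_grid <- gridTransform(stack)
  cellOf <- function(lon, lat) {
    cbind(row = pmin(pmax(floor((tr_grid[2] - lat) / tr_grid[4]) + 1L, 1L),
                     gridDim(stack)[1L]),
          col = pmin(pmax(floor((lon - tr_grid[1]) / tr_grid[3]) + 1L, 1L),
                     gridDim(stack)[2L]))
  }
  pres_cells <- cellOf(occ_t$lon, occ_t$lat)
  pres_vals <- extractCells(stack, pres_cells)
  keep <- complete.cases(pres_vals)
  pres_vals <- pres_vals[keep, , drop = FALSE]

  ## 3. background --------------------------------------------------------
  bg <- sampleBackground(stack, B = config$background, seed = seed_for(5L))
  bg_vals <- extractCells(stack, as.matrix(bg[, c("row", "col")]))
  note("background", TRUE, B = nrow(bg))

  ## 4. screen ------------------------------------------------------------
  all_vals <- rbind(pres_vals, bg_vals)
  prelim <- fitFromValues(pres_vals, rbind(pres_vals, bg_vals), "LQ", 1,
                          K = config$feature_knots,
                          max_iter = config$max_iter, tol = config$tol)
  imp <- data.frame(percent_contribution = percentContribution(prelim),
                    permutation_importance =
                      permutationImportance(prelim, pres_vals, bg_vals,
                                            seed = seed_for(6L)))
  sel <- selectVariables(all_vals, imp)
  vars <- sel$kept
  if (length(vars) < 1L) stop("screening removed every variable")
  pres_vals <- pres_vals[, vars, drop = FALSE]
  bg_vals <- bg_vals[, vars, drop = FALSE]
  write.csv(data.frame(variable = rownames(imp), imp),
            file.path(out, "screening_importance.csv"), row.names = FALSE)
  emit("screening_importance.csv")
  note("screen", TRUE, kept = paste(vars, collapse = ","),
       dropped = paste(sel$dropped$variable, collapse = ","))

  ## 5. tune --------------------------------------------------------------
  splits <- makeSplits(nrow(pres_vals), R = config$replicates,
                       seed = seed_for(7L))
  land_cells <- validCells(stack)
  land_vals <- extractCells(stack, land_cells)[, vars, drop = FALSE]
  arch <- tuneMaxent(pres_vals, bg_vals, landscape_vals = land_vals,
                     splits = splits, K = config$feature_knots,
                     max_iter = config$max_iter, tol = config$tol,
                     generations = config$tune$generations,
                     pop_size = config$tune$pop_size, seed = seed_for(8L),
                     exhaustive = isTRUE(config$tune$exhaustive),
                     rm_indices = config$tune$rm_indices,
                     fc_indices = config$tune$fc_indices)
  writeArchive(arch, file.path(out, "archive.json")); emit("archive.json")
  g <- selectedGenotype(arch)
  note("tune", TRUE, rm = g$rm, fc = g$fc,
       evaluated = nrow(archiveTable(arch)))

  ## 6. final fit on all thinned presences --------------------------------
  model <- fitFromValues(pres_vals, rbind(pres_vals, bg_vals), g$fc, g$rm,
                         K = config$feature_knots,
                         max_iter = config$max_iter, tol = config$tol)
  s_pres <- predictCloglog(model, pres_vals)
  s_bg <- predictCloglog(model, bg_vals)
  tau_mtss <- mtssThreshold(s_pres, s_bg)
  writeModelJson(model, file.path(out, "model.json")); emit("model.json")
  note("fit", TRUE, tau_mtss = tau_mtss,
       k = sum(modelCoefficients(model) != 0))

  ## 7. project every scenario --------------------------------------------
  suit <- list()
  for (nm in names(scen_stacks)) {
    sc_vals <- extractCells(scen_stacks[[nm]], land_cells)[, vars, drop = FALSE]
    P <- matrix(NA_real_, gridDim(stack)[1L], gridDim(stack)[2L])
    P[land_cells] <- predictCloglog(model, sc_vals)
    suit[[nm]] <- P
    writeAsciiGrid(P, tr_grid, file.path(out, paste0("suitability_", nm, ".asc")))
    emit(paste0("suitability_", nm, ".asc"))
  }
  note("project", TRUE, scenarios = paste(names(suit), collapse = ","))

  ## 8. MESS ---------------------------------------------------------------
  reference <- rbind(pres_vals, bg_vals)
  mess_masks <- list()
  for (nm in names(scen_stacks)) {
    ms <- messSurface(reference, scen_stacks[[nm]])
    mess_masks[[nm]] <- extrapolationMask(ms)
    writeAsciiGrid(ms$S, tr_grid, file.path(out, paste0("mess_S_", nm, ".asc")))
    emit(paste0("mess_S_", nm, ".asc"))
  }
  note("mess", TRUE)

  ## 9. classify ------------------------------------------------------------
  breaks <- switch(config$breaks,
    preset = presetBreaks(),
    equal = makeBreaks(suit$current, tau_mtss, "equal"),
    quantile = makeBreaks(suit$current, tau_mtss, "quantile"),
    stop("breaks must be preset, equal or quantile"))
  classes <- lapply(suit, classifySuitability, breaks = breaks)
  for (nm in names(classes)) {
    writeAsciiGrid(classes[[nm]], tr_grid,
                   file.path(out, paste0("classes_", nm, ".asc")))
    emit(paste0("classes_", nm, ".asc"))
  }
  note("classify", TRUE, breaks = paste(signif(breaks, 6), collapse = "/"))

  ## 10. dynamics ------------------------------------------------------------
  at <- areaTable(classes, tr_grid)
  write.csv(at, file.path(out, "area_table.csv"), row.names = FALSE)
  emit("area_table.csv")
  cents <- do.call(rbind, lapply(names(classes), function(nm) {
    ct <- habitatCentroid(classes[[nm]] > 0, tr_grid)
    data.frame(period = nm, lon = ct$lon, lat = ct$lat)
  }))
  if (nrow(cents) >= 2L) {
    mig <- centroidMigration(cents)
    cents <- merge(cents, rbind(data.frame(to = cents$period[1L],
                                           distance_km = NA, bearing_deg = NA),
                                mig[, c("to", "distance_km", "bearing_deg")]),
                   by.x = "period", by.y = "to", sort = FALSE)
  }
  write.csv(cents, file.path(out, "centroids.csv"), row.names = FALSE)
  emit("centroids.csv")
  for (nm in setdiff(names(classes), "current")) {
    cm <- changeMap(classes$current > 0, classes[[nm]] > 0)
    writeAsciiGrid(cm, tr_grid, file.path(out, paste0("change_", nm, ".asc")))
    emit(paste0("change_", nm, ".asc"))
  }
  note("dynamics", TRUE)

  ## 11. risk ---------------------------------------------------------------
  if (length(densities)) {
    risk_rows <- list()
    for (sp_name in names(densities)) {
      rmap <- riskMap(suit$current, mess_masks$current, tau_mtss,
                      densities[[sp_name]], tr_grid)
      writeAsciiGrid(rmap$classes, tr_grid,
                     file.path(out, paste0("risk_class_", sp_name, ".asc")))
      emit(paste0("risk_class_", sp_name, ".asc"))
      risk_rows[[sp_name]] <- data.frame(
        species = sp_name,
        break1 = rmap$breaks[1L] %||% NA, break2 = rmap$breaks[2L] %||% NA,
        t(rmap$areas_km2), total_risk_km2 = rmap$total_risk_km2)
    }
    write.csv(do.call(rbind, risk_rows), file.path(out, "risk_areas.csv"),
              row.names = FALSE)
    emit("risk_areas.csv")
    note("risk", TRUE, species = paste(names(densities), collapse = ","))
  } else {
    note("risk", TRUE, skipped = "no density inputs configured")
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Serialise a fitted model to JSON
#'
#' Feature spec (bounds, fc, knots), coefficients, penalties, entropy and
#' partition value, so projections are reproducible from the file.
#'
#' @param model a MaxentModel.
#' @param path output file.
#' @export
writeModelJson <- function(model, path) {
  jsonlite::write_json(list(
    fc = model@fc, rm = model@rm, K = model@spec$K,
    bounds = as.data.frame(model@spec$bounds),
    features = model@spec$features,
    lambda = as.list(model@lambda[model@lambda != 0]),
    beta = as.list(model@beta), logZ = model@logZ, H = model@H,
    n_cells = model@nCells,
    var_means = as.list(model@varMeans)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
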