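#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

pipelineDefaults <- function() {
  list(
    seed = 1L,
    geometry = list(length = 500, diameter = 180, voxelEdge = 10,
                    shape = "ellipsoid"),
    transport = list(D = 1.0e-9, D_units = "m2/s", R = 0.02,
                     kConv = 0.26 / 21),
    profile = list(cLo = 3, cHi = 20, peakSlope0 = 0.028,
                   peakSlope180 = 0.023, wallX = 0),
    constraints = list(list(polarity = "AP", equivalentO2 = 10, offset = 0),
                       list(polarity = "PA", equivalentO2 = 8.3,
                            offset = 0)),
    generator = list(n = 50, o2Lo = 5.5, o2Hi = 20, noiseSd = 0.5,
                     watch = 500, frameInterval = 3),
    sensitivity = list(),
    ERange = c(1e-7, 1e-3)
  )
}

mergeSection <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("schema error: unknown key(s) in section '", section, "': ",
         paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills missing sections with defaults (the published simulation values:
#' D = 1.0e-9 m2/s, R = 0.02 mol/(m3 s), a 500 x 180 x 180 um embryo at
#' 10 um voxels, the 3-20\% device profile, and the two reference
#' equivalence constraints), rejects unknown keys, converts units (a
#' diffusivity given with \code{D_units: "cm2/s"} is converted to m2/s) and
#' checks that physical constants are positive.
#'
#' @param raw a named list, or the path of a YAML file
#' @return the normalized configuration list
#' @examples
#' validateConfig(list())$transport$D   # 1e-9
#' @export
validateConfig <- function(raw = list()) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("schema error: unknown top-level key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- defaults
  for (s in c("geometry", "transport", "profile", "generator"))
    cfg[[s]] <- mergeSection(defaults[[s]], raw[[s]], s)
  for (s in c("seed", "constraints", "sensitivity", "ERange"))
    if (!is.null(raw[[s]])) cfg[[s]] <- raw[[s]]

  if (identical(cfg$transport$D_units, "cm2/s")) {
    cfg$transport$D <- cfg$transport$D * 1e-4
    cfg$transport$D_units <- "m2/s"
  } else if (!identical(cfg$transport$D_units, "m2/s")) {
    stop("schema error: D_units must be 'm2/s' or 'cm2/s'")
  }
  with(cfg$transport, {
    if (D <= 0 || R <= 0 || kConv <= 0)
      stop("validation error: transport constants must be positive")
  })
  with(cfg$geometry, {
    if (length <= 0 || diameter <= 0 || voxelEdge <= 0)
      stop("validation error: geometry dimensions must be positive")
  })
  for (cn in cfg$constraints)
    if (is.null(cn$polarity) || is.null(cn$equivalentO2))
      stop("validation error: each constraint needs polarity and ",
           "equivalentO2")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic inputs under one seed: generate a
#' migration-time dataset, quantify synthetic trajectories and stripe
#' passages, refit the dose-response curve, estimate the membrane
#' permeability from the equivalence constraints, and (if variations are
#' configured) run the sensitivity analysis.  A single JSON summary is
#' written; reruns under the same configuration are byte-identical.
#'
#' @param config a configuration list or YAML path (see [validateConfig()])
#' @param outputDir directory for \code{summary.json} and per-stage CSVs;
#'   NULL skips writing
#' @param verbose log stage progress to stderr
#' @return the summary list, invisibly
#' @export
runPipeline <- function(config = list(), outputDir = NULL, verbose = TRUE) {
  cfg <- validateConfig(config)
  say <- function(...) if (verbose) message("[embryOx] ", ...)
  stamp <- function(stage, t0)
    say(stage, " done in ", format(round(as.numeric(Sys.time()) - t0, 2)),
        " s")

  set.seed(cfg$seed)
  truth <- referenceDoseResponse()

  t0 <- as.numeric(Sys.time())
  say("stage generate")
  gen <- cfg$generator
  dataset <- genMigrationDataset(gen$n, truth, c(gen$o2Lo, gen$o2Hi),
                                 noiseSd = gen$noiseSd, watch = gen$watch)
  stamp("generate", t0)

  t0 <- as.numeric(Sys.time())
  say("stage quantify-tracks")
  quant <- lapply(c(normoxia = 20, hypoxia = 8), function(o2) {
    tr <- genTrajectory(o2, truth, frameInterval = gen$frameInterval)
    sp <- genStripePassages(o2, truth)
    list(o2 = o2,
         migrationTime1090 = migrationTime1090(tr),
         meanVelocity = meanVelocity(tr),
         stripeMigrationTime = stripeMigrationTime(sp))
  })
  stamp("quantify-tracks", t0)

  t0 <- as.numeric(Sys.time())
  say("stage fit-dose-response")
  fit <- fitDoseResponse(dataset)
  stamp("fit-dose-response", t0)

  t0 <- as.numeric(Sys.time())
  say("stage solve + estimate-permeability")
  geom <- embryoGeometry(cfg$geometry$length, cfg$geometry$diameter,
                         cfg$geometry$voxelEdge, cfg$geometry$shape)
  grid <- voxelize(geom)
  params <- transportParams(D = cfg$transport$D, R = cfg$transport$R,
                            kConv = cfg$transport$kConv)
  profile <- deviceProfile(cfg$profile$cLo, cfg$profile$cHi,
                           cfg$profile$peakSlope0, cfg$profile$peakSlope180,
                           cfg$profile$wallX)
  constraints <- lapply(cfg$constraints, function(cn)
    equivalenceConstraint(cn$polarity, cn$equivalentO2,
                          offset = if (is.null(cn$offset)) 0 else cn$offset))
  est <- estimatePermeability(constraints, params, grid, profile,
                              ERange = cfg$ERange)
  stamp("solve + estimate-permeability", t0)

  sens <- NULL
  if (length(cfg$sensitivity)) {
    t0 <- as.numeric(Sys.time())
    say("stage sensitivity (", length(cfg$sensitivity), " variation(s))")
    sens <- sensitivityAnalysis(params, cfg$sensitivity, constraints,
                                grid, profile, ERange = cfg$ERange)
    stamp("sensitivity", t0)
  }

  summary <- list(
    seed = cfg$seed,
    parameters = list(D_m2_per_s = params@D, R_mol_m3_s = params@R,
                      kConv = params@kConv,
                      geometry_um = c(cfg$geometry$length,
                                      cfg$geometry$diameter,
                                      cfg$geometry$diameter),
                      voxelEdge_um = cfg$geometry$voxelEdge,
                      nElements = nVoxels(grid)),
    doseResponse = as.list(coef(fit)),
    migrationTimes = quant,
    permeability = list(E_m_per_s = est@EHat,
                        E_cm_per_s = est@EHat * 100,
                        objective = est@objective,
                        residuals = as.numeric(est@residuals)),
    sensitivity = if (!is.null(sens)) sens else list()
  )

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dataset, file.path(outputDir, "migration_dataset.csv"),
                     row.names = FALSE)
    write_json(summary, file.path(outputDir, "summary.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
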