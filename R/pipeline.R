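# End-to-end pipeline: configuration, staged execution, provenance, and
# deterministic toy fixtures for tests.

#' @importFrom yaml read_yaml write_yaml
NULL

#' Default run configuration
#'
#' All model and simulation parameters with their standard values: n = 6,
#' sigma_c = 1 (1.04 um physically), l = 0.025 sigma_c, T = 24 C, 200 mM
#' NaCl, the 11-nt linker pair, strand number "calibrate", 60k grid
#' sites, and the production MC protocol (1e5 equilibration, 1e7
#' production sweeps, records every 50 sweeps, 20 runs).  Override any
#' entry via `modifyList()` or a YAML file.
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    alpha = 0.63,
    n = 6,
    sigma_c = 1,
    sigma_c_um = 1.04,
    l = 0.025,
    temperature_C = 24,
    salt_M = 0.2,
    sticky_end = list(seqA = "GTAGAAGTAGG", seqB = "CCTACTTCTAC"),
    tail_penalty = 0,
    n_gamma = "calibrate",
    n_delta = NULL,
    rho0_M = 1,
    grid = list(target_sites = 60000, seed = 1, k = 6),
    omega = list(n_samples = 2e5, seed = 1),
    mc = list(equilibration = 1e5, production = 1e7, record_every = 50,
              n_runs = 20, base_seed = 1),
    n_spheres = NULL,      # NULL: coordination number observed for alpha
    quasi2d = "auto",
    calibration = list(max_rate = 1e-6, n_max = 400)
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over \code{\link{defaultConfig}}.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultConfig(), user)
  .checkConfig(cfg)
  cfg
}

.checkConfig <- function(cfg) {
  pos <- c("alpha", "n", "sigma_c", "l", "salt_M", "rho0_M")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop("config: ", p, " must be a positive number")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages duplex thermodynamics -> grid -> configurational
#' integrals -> landscape (-> strand-number calibration when `n_gamma =
#' "calibrate"`) -> surface MC ensemble -> observables, writing all
#' artifacts (CSV/XYZ/JSON) under `outDir` along with a provenance log
#' (configuration hash and seeds).  With `config$mc$production = 0` the
#' pipeline stops after the landscape.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param outDir output directory (created if missing); NULL to skip
#'   writing and return objects only.
#' @return list with elements `thermo`, `grid`, `landscape`,
#'   `calibration`, `trajectories`, `observables` (stages that did not
#'   run are NULL).
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL) {
  .checkConfig(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  tempK <- 273.15 + config$temperature_C
  thermo <- stage("thermo", duplexDG0(
    config$sticky_end$seqA, config$sticky_end$seqB,
    temperature = tempK, saltM = config$salt_M,
    tailPenalty = config$tail_penalty))
  grid <- stage("grid", buildSuperballGrid(
    n = config$n, sigmaC = config$sigma_c,
    targetSites = config$grid$target_sites, seed = config$grid$seed,
    k = config$grid$k))
  rho0 <- rho0FromMolar(config$rho0_M, config$sigma_c_um)
  mcInt <- list(nSamples = config$omega$n_samples, seed = config$omega$seed)

  calib <- NULL
  if (identical(config$n_gamma, "calibrate")) {
    calib <- stage("calibrate", calibrateStrandNumber(
      grid, alphaRef = 0.63, betaDG0 = thermo@betaDG0, rho0 = rho0,
      l = config$l, maxRate = config$calibration$max_rate,
      nMax = config$calibration$n_max, mc = mcInt))
    nGamma <- scaleStrandCount(calib$nGamma, config$alpha)
    nDelta <- calib$nDelta
  } else {
    nGamma <- as.integer(config$n_gamma)
    nDelta <- if (is.null(config$n_delta))
      as.integer(round(strandDensityRatio(grid) * config$n_gamma))
    else as.integer(config$n_delta)
  }
  params <- bondParams(betaDG0 = thermo@betaDG0, rho0 = rho0,
                       nGamma = nGamma, nDelta = nDelta, l = config$l)
  landscape <- stage("landscape", computeLandscape(
    grid, params, config$alpha, temperature = tempK, mc = mcInt))

  trajectories <- NULL; obs <- NULL
  if (config$mc$production > 0) {
    nSpheres <- if (is.null(config$n_spheres))
      sphereCountForAlpha(config$alpha) else config$n_spheres
    trajectories <- stage("simulate", runEnsemble(
      grid, landscape, nSpheres, nRuns = config$mc$n_runs,
      nSweeps = config$mc$production,
      recordEvery = config$mc$record_every,
      equilibration = config$mc$equilibration,
      baseSeed = config$mc$base_seed, quasi2d = config$quasi2d))
    obs <- stage("observables", list(
      c_r = positionAutocorrelation(trajectories),
      delta_r = meanDisplacement(trajectories),
      crossings = vapply(trajectories,
                         function(t) sum(countFaceCrossings(t)),
                         numeric(1))))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    exportGrid(grid, file.path(outDir, "run"))
    exportLandscape(landscape, grid, file.path(outDir, "run"))
    if (!is.null(trajectories)) {
      for (r in seq_along(trajectories))
        exportTrajectoryXYZ(trajectories[[r]],
                            file.path(outDir, sprintf("run-traj%02d", r)))
      write.csv(obs$c_r, file.path(outDir, "run-cr.csv"),
                row.names = FALSE)
      write.csv(data.frame(alpha = config$alpha, delta_r = obs$delta_r,
                           n_runs = length(trajectories)),
                file.path(outDir, "run-deltar.csv"), row.names = FALSE)
    }
    prov <- list(format = .fmtVersion, kind = "provenance",
                 config = config,
                 configHash = .fnv1a(deparse(config)),
                 nGamma = nGamma, nDelta = nDelta,
                 packageVersion =
                   as.character(utils::packageVersion("FlexColloid")))
    write_json(prov, file.path(outDir, "run-provenance.json"),
               auto_unbox = TRUE, digits = NA)
  }
  list(thermo = thermo, grid = grid, landscape = landscape,
       calibration = calib, trajectories = trajectories,
       observables = obs)
}

#' Deterministic toy fixtures
#'
#' Small objects for tests and examples: `toy-grid` (a ~500-site grid),
#' `toy-landscape` (a two-level step landscape over the toy grid, low on
#' the +x face), `toy-trajectory` (a 100-record alternation between two
#' sites with known autocorrelation), `toy-duplex` (the ACGT
#' self-complementary 4-mer).
#'
#' @param kind one of `"toy-grid"`, `"toy-landscape"`,
#'   `"toy-trajectory"`, `"toy-duplex"`.
#' @param seed integer seed.
#' @return the fixture object.
#' @export
makeFixture <- function(kind = c("toy-grid", "toy-landscape",
                                 "toy-trajectory", "toy-duplex"),
                        seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    "toy-grid" = buildSuperballGrid(n = 6, targetSites = 500, seed = seed),
    "toy-landscape" = {
      grid <- buildSuperballGrid(n = 6, targetSites = 500, seed = seed)
      betaF <- ifelse(faceLabels(grid) == "+x", -3, -1)
      new("Landscape", gridId = grid@id, alpha = 0.63,
          temperature = 297.15, betaFbond = betaF,
          betaDGcnf = rep(0, nSites(grid)),
          betaDF = betaF - min(betaF),
          params = list(nGamma = 1L, nDelta = 1L, betaDG0 = 0,
                        rho0 = 1, l = 0.025, omegaGamma = 1,
                        omegaDelta = 1, nSamples = 0, seed = seed))
    },
    "toy-trajectory" = {
      p1 <- c(0.5, 0, 0)
      p2 <- surfacePoint(c(1, 0.4, 0))
      coords <- array(NA_real_, dim = c(100, 1, 3))
      for (f in 1:100) coords[f, 1, ] <- if (f %% 2) p1 else p2
      new("SurfaceTrajectory", steps = seq(0, by = 50, length.out = 100),
          sites = matrix(NA_integer_, 100, 1), coords = coords,
          faces = matrix("+x", 100, 1), alpha = 0.63,
          gridId = "toy", quasi2d = FALSE, seed = as.numeric(seed),
          acceptanceRate = NA_real_)
    },
    "toy-duplex" = duplexDG0("ACGT", "ACGT")
  )
}
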