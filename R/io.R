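# Export/import round trips for grids, landscapes and trajectories.
# CSV + JSON sidecars for tabular artifacts, extended XYZ for trajectories.

#' @importFrom jsonlite write_json read_json toJSON
NULL

.fmtVersion <- "flexcolloid-1"

# small deterministic rolling hash for provenance strings
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Export / import a surface grid
#'
#' Writes `<prefix>-sites.csv` (site index, position, normal, curvature,
#' face label, orbit), `<prefix>-edges.csv` (symmetric edge list) and a
#' JSON sidecar with the construction parameters so the grid can be
#' regenerated or re-imported verbatim.
#'
#' @param grid a \linkS4class{SuperballGrid}.
#' @param prefix output path prefix.
#' @return `exportGrid` the sidecar path (invisibly); `importGrid` the
#'   reconstructed grid.
#' @export
exportGrid <- function(grid, prefix) {
  s <- grid@sites
  df <- data.frame(site = seq_len(nrow(s)), s, orbit = grid@orbit)
  write.csv(df, paste0(prefix, "-sites.csv"), row.names = FALSE)
  from <- rep.int(seq_along(grid@adjacency), lengths(grid@adjacency))
  to <- unlist(grid@adjacency, use.names = FALSE)
  write.csv(data.frame(from = from, to = to),
            paste0(prefix, "-edges.csv"), row.names = FALSE)
  meta <- list(format = .fmtVersion, kind = "grid", n = grid@n,
               sigmaC = grid@sigmaC, targetSites = grid@targetSites,
               seed = grid@seed, id = grid@id,
               nSites = nrow(s))
  write_json(meta, paste0(prefix, "-grid.json"), auto_unbox = TRUE)
  invisible(paste0(prefix, "-grid.json"))
}

#' @rdname exportGrid
#' @export
importGrid <- function(prefix) {
  meta <- read_json(paste0(prefix, "-grid.json"), simplifyVector = TRUE)
  if (!identical(meta$format, .fmtVersion) || !identical(meta$kind, "grid"))
    stop("format error: not a ", .fmtVersion, " grid sidecar")
  df <- read.csv(paste0(prefix, "-sites.csv"), stringsAsFactors = FALSE)
  ed <- read.csv(paste0(prefix, "-edges.csv"))
  adj <- unname(split(as.integer(ed$to), ed$from))
  orbit <- as.integer(df$orbit)
  sites <- df[, c("x", "y", "z", "nx", "ny", "nz", "gamma", "face")]
  new("SuperballGrid", n = meta$n, sigmaC = meta$sigmaC, sites = sites,
      adjacency = adj, orbit = orbit,
      orbitRep = match(seq_len(max(orbit)), orbit),
      targetSites = meta$targetSites, seed = meta$seed, id = meta$id)
}

#' Export / import a free-energy landscape
#'
#' CSV keyed by site index (beta*F_bond, beta*dF, configurational cost,
#' Gaussian curvature, face label) plus a JSON sidecar with the model
#' parameters; the CSV is directly usable for barrier-versus-curvature
#' scatter plots.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param grid the grid it was computed on.
#' @param prefix output path prefix.
#' @return `exportLandscape` the sidecar path (invisibly);
#'   `importLandscape` the reconstructed landscape.
#' @export
exportLandscape <- function(landscape, grid, prefix) {
  df <- data.frame(site = seq_len(nSites(grid)),
                   beta_F_bond = landscape@betaFbond,
                   beta_dF = landscape@betaDF,
                   beta_dG_cnf = landscape@betaDGcnf,
                   gamma = siteCurvature(grid),
                   face = faceLabels(grid))
  write.csv(df, paste0(prefix, "-landscape.csv"), row.names = FALSE)
  meta <- c(list(format = .fmtVersion, kind = "landscape",
                 gridId = landscape@gridId, alpha = landscape@alpha,
                 temperature = landscape@temperature),
            landscape@params)
  write_json(meta, paste0(prefix, "-landscape.json"), auto_unbox = TRUE,
             digits = NA)
  invisible(paste0(prefix, "-landscape.json"))
}

#' @rdname exportLandscape
#' @export
importLandscape <- function(prefix) {
  meta <- read_json(paste0(prefix, "-landscape.json"),
                    simplifyVector = TRUE)
  if (!identical(meta$format, .fmtVersion) ||
      !identical(meta$kind, "landscape"))
    stop("format error: not a ", .fmtVersion, " landscape sidecar")
  df <- read.csv(paste0(prefix, "-landscape.csv"))
  params <- meta[c("nGamma", "nDelta", "betaDG0", "rho0", "l",
                   "omegaGamma", "omegaDelta", "nSamples", "seed")]
  new("Landscape", gridId = meta$gridId, alpha = meta$alpha,
      temperature = meta$temperature, betaFbond = df$beta_F_bond,
      betaDGcnf = df$beta_dG_cnf, betaDF = df$beta_dF, params = params)
}

#' Export / import a trajectory as extended XYZ
#'
#' One frame per record; the comment line carries the MC sweep index; one
#' atom line per sphere tagged `S<sphere>` with the contact-point
#' coordinates.  A JSON sidecar carries run metadata (alpha, seed,
#' quasi-2D flag, grid identity).  Re-import reproduces steps and
#' coordinates exactly (site indices and face labels are restored from
#' the sidecar's grid when supplied).
#'
#' @param traj a \linkS4class{SurfaceTrajectory}.
#' @param prefix output path prefix.
#' @param grid optional grid used on import to restore site indices and
#'   face labels.
#' @return `exportTrajectoryXYZ` the xyz path (invisibly);
#'   `importTrajectoryXYZ` the reconstructed trajectory.
#' @export
exportTrajectoryXYZ <- function(traj, prefix) {
  ns <- ncol(traj@sites)
  con <- file(paste0(prefix, ".xyz"), "w")
  on.exit(close(con))
  for (f in seq_along(traj@steps)) {
    writeLines(as.character(ns), con)
    writeLines(sprintf("step=%d", as.integer(traj@steps[f])), con)
    for (s in seq_len(ns)) {
      writeLines(sprintf("S%d %.12g %.12g %.12g", s,
                         traj@coords[f, s, 1], traj@coords[f, s, 2],
                         traj@coords[f, s, 3]), con)
    }
  }
  meta <- list(format = .fmtVersion, kind = "trajectory",
               gridId = traj@gridId, alpha = traj@alpha,
               quasi2d = traj@quasi2d, seed = traj@seed,
               acceptanceRate = traj@acceptanceRate,
               nSpheres = ns, nRecords = length(traj@steps))
  write_json(meta, paste0(prefix, "-traj.json"), auto_unbox = TRUE,
             digits = NA)
  invisible(paste0(prefix, ".xyz"))
}

#' @rdname exportTrajectoryXYZ
#' @export
importTrajectoryXYZ <- function(prefix, grid = NULL) {
  meta <- read_json(paste0(prefix, "-traj.json"), simplifyVector = TRUE)
  if (!identical(meta$format, .fmtVersion) ||
      !identical(meta$kind, "trajectory"))
    stop("format error: not a ", .fmtVersion, " trajectory sidecar")
  lines <- readLines(paste0(prefix, ".xyz"))
  ns <- meta$nSpheres; nr <- meta$nRecords
  stopifnot(length(lines) == nr * (ns + 2))
  steps <- numeric(nr)
  coords <- array(NA_real_, dim = c(nr, ns, 3))
  sites <- matrix(NA_integer_, nr, ns)
  faces <- matrix(NA_character_, nr, ns)
  pos <- 1L
  for (f in seq_len(nr)) {
    if (as.integer(lines[pos]) != ns) stop("format error: bad frame header")
    steps[f] <- as.numeric(sub("step=", "", lines[pos + 1L]))
    for (s in seq_len(ns)) {
      parts <- strsplit(lines[pos + 1L + s], " +")[[1]]
      coords[f, s, ] <- as.numeric(parts[2:4])
    }
    pos <- pos + ns + 2L
  }
  if (!is.null(grid)) {
    for (f in seq_len(nr)) for (s in seq_len(ns)) {
      sites[f, s] <- nearestSite(grid, coords[f, s, ])
      faces[f, s] <- faceLabels(grid)[sites[f, s]]
    }
  }
  new("SurfaceTrajectory", steps = steps, sites = sites, coords = coords,
      faces = faces, alpha = meta$alpha, gridId = meta$gridId,
      quasi2d = meta$quasi2d, seed = meta$seed,
      acceptanceRate = if (is.null(meta$acceptanceRate)) NA_real_
                       else meta$acceptanceRate)
}

#' Export a trajectory as compact CSV
#'
#' Tidy long format: step, sphere, site index, contact-point coordinates
#' and face label.
#'
#' @param traj a \linkS4class{SurfaceTrajectory}.
#' @param path output csv path.
#' @export
exportTrajectoryCSV <- function(traj, path) {
  ns <- ncol(traj@sites)
  rows <- do.call(rbind, lapply(seq_len(ns), function(s) {
    data.frame(step = traj@steps, sphere = s, site = traj@sites[, s],
               x = traj@coords[, s, 1], y = traj@coords[, s, 2],
               z = traj@coords[, s, 3], face = traj@faces[, s])
  }))
  write.csv(rows[order(rows$step, rows$sphere), ], path,
            row.names = FALSE)
  invisible(path)
}
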