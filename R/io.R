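# File I/O: multi-page TIFF stacks, CSV kymographs/trajectories, YAML
# configuration, and PNG rendering.

#' Read/write multi-page TIFF stacks
#'
#' Stacks are written as one 32-bit float page per frame (binary masks as
#' 8-bit). Values are written as-is; TIFF float pages carry arbitrary units.
#'
#' @param stack 3D array (rows x cols x frames) or list of matrices.
#' @param file path.
#' @return \code{readStackTiff}: a 3D array; \code{writeStackTiff}:
#'   invisibly, the path.
#' @export
writeStackTiff <- function(stack, file) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- stack[, , k]
    storage.mode(m) <- "double"
    m
  })
  isMask <- all(stack %in% c(0, 1))
  if (isMask) tiff::writeTIFF(pages, file, bits.per.sample = 8L)
  else tiff::writeTIFF(pages, file, bits.per.sample = 32L,
                       reduce = FALSE)
  invisible(file)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  simplify2array(pages)
}

#' Save a simulation to disk
#'
#' Writes the mask stack and one stack per component as multi-page TIFF, the
#' per-frame volume as CSV, and a JSON sidecar with the solver metadata.
#'
#' @param sim output of \code{\link{simulateCell}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeStackTiff(sim$masks, file.path(dir, "mask.tif"))
  for (cc in names(sim$fields))
    writeStackTiff(sim$fields[[cc]], file.path(dir, paste0(cc, ".tif")))
  write.csv(data.frame(frame = seq_along(sim$volume), volume = sim$volume),
            file.path(dir, "volume.csv"), row.names = FALSE)
  cfg <- sim$cfg
  meta <- list(model = modelName(sim$model),
               components = components(sim$model),
               dt = cfg@dt, dx = cfg@dx, noiseAmp = cfg@noiseAmp,
               noiseScaling = cfg@noiseScaling,
               rdItersPerEvent = cfg@rdItersPerEvent,
               saveEvery = cfg@saveEvery, seed = cfg@seed,
               nFrames = length(sim$volume),
               actinMode = sim$morpho@actinMode)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a kymograph (or any trajectories x frames matrix) to CSV
#'
#' @param kym a \linkS4class{Kymograph} or matrix.
#' @param file path.
#' @return Invisibly, the path.
#' @export
writeKymographCsv <- function(kym, file) {
  M <- if (is(kym, "Kymograph")) kym@data else kym
  df <- as.data.frame(M)
  names(df) <- paste0("frame", seq_len(ncol(M)))
  df <- cbind(trajectory = seq_len(nrow(M)), df)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a trajectory bundle to CSV (long format)
#'
#' Columns: trajectory id, frame, x, y, velocity, signal.
#'
#' @param bundle a \linkS4class{TrajectoryBundle}.
#' @param file path.
#' @return Invisibly, the path.
#' @export
writeTrajectoriesCsv <- function(bundle, file) {
  nt <- nrow(bundle@x); nf <- ncol(bundle@x)
  df <- data.frame(trajectory = rep(seq_len(nt), nf),
                   frame = rep(seq_len(nf), each = nt),
                   x = as.vector(bundle@x), y = as.vector(bundle@y),
                   velocity = as.vector(bundle@velocity),
                   signal = as.vector(bundle@signal))
  df <- df[!is.na(df$x), ]
  df <- df[order(df$trajectory, df$frame), ]
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Render a kymograph to PNG
#'
#' @param kym a \linkS4class{Kymograph}.
#' @param file PNG path.
#' @return Invisibly, the path.
#' @export
plotKymograph <- function(kym, file) {
  M <- kym@data
  grDevices::png(file, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  Mp <- M
  Mp[!is.finite(Mp)] <- 0
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), Mp,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "trajectory index", ylab = "time (frames)",
                  main = paste(kym@kind, "kymograph"))
  pk <- kym@peaks
  if (nrow(pk)) graphics::points(pk$trajectory, pk$frame, pch = 20,
                                 col = "red")
  invisible(file)
}

#' Read/write YAML configuration
#'
#' @param config named list.
#' @param path YAML file path.
#' @return \code{readConfig}: the named list; \code{writeConfig}: invisibly,
#'   the path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  yaml::read_yaml(path)
}
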