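# Raster and configuration I/O plus the run manifest.

#' Read and write habitat rasters in ESRI ASCII grid format
#'
#' The dialect is the standard six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by a whitespace-separated
#' integer matrix, one row per line, northernmost row first.  Cell size
#' is fixed at 1 m.  Unknown habitat codes are rejected with the
#' offending codes and first offending cell named.
#'
#' @param path file path.
#' @param classes class attribute table (see
#'   \code{\link{voleHabitatClasses}}).
#' @return \code{readHabitatRaster}: a \linkS4class{HabitatGrid}.
#' @export
readHabitatRaster <- function(path, classes = voleHabitatClasses()) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: too short")
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys) || any(is.na(vals[need])))
    stop("malformed ESRI ASCII grid header")
  if (vals[["cellsize"]] != 1) stop("cellsize must be 1 m")
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) stop("non-rectangular body: expected ", nr,
                               " rows, found ", length(body))
  rows <- lapply(body, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(rows) != nc))
    stop("non-rectangular body: row widths differ from ncols")
  m <- do.call(rbind, rows)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # file stores north-up; row 1 = y 0
  bad <- setdiff(unique(as.vector(m)), classes$code)
  if (length(bad)) {
    cell <- which(matrix(m %in% bad, nr, nc), arr.ind = TRUE)[1, ]
    stop("unknown habitat code(s) ", paste(bad, collapse = ", "),
         "; first at cell (x=", cell[2] - 1, ", y=", cell[1] - 1, ")")
  }
  habitatGrid(m, classes)
}

#' @rdname readHabitatRaster
#' @param grid a \linkS4class{HabitatGrid}.
#' @export
writeHabitatRaster <- function(grid, path) {
  m <- grid@codes
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           "xllcorner 0", "yllcorner 0", "cellsize 1", "NODATA_value -9999")
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1, paste,
                collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# small djb2-style hash over a serialized object, for run manifests
.configHash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: scenario id, seed,
#' replicate count, scale factor, the parameter values, and a hash of
#' the full configuration.  Written as JSON next to the run outputs.
#'
#' @param scenario a \linkS4class{VoleScenario}.
#' @param params a \linkS4class{VoleParams}.
#' @param seed integer seed used.
#' @param dir output directory (created if needed).
#' @param n_replicates replicate count recorded.
#' @return the manifest path, invisibly.
#' @export
writeRunManifest <- function(scenario, params, seed, dir,
                             n_replicates = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- list(scenario = scenario@id, seed = seed,
              n_replicates = n_replicates,
              scale_factor = scenario@scaleFactor,
              years_total = scenario@yearsTotal,
              years_burn_in = scenario@yearsBurnIn,
              predators = length(scenario@predators) > 0,
              params = as.list(c(paramValues(params), paramAux(params))))
  cfg$config_hash <- .configHash(cfg)
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}
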