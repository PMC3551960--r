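#' Write an environmental layer as an ESRI ASCII grid
#'
#' Plain-text raster with `ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header and rows ordered north to south. Values are written
#' with 17 significant digits so a write-read round trip reproduces doubles
#' exactly.
#'
#' @param grid An [env_grid()].
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_env_layer <- function(grid, path) {
  spec <- grid$spec
  nodata <- -9999
  vals <- grid$values
  if (any(vals == nodata, na.rm = TRUE)) {
    stop("a data value collides with the nodata marker -9999")
  }
  header <- c(
    sprintf("ncols %d", spec$n_lon),
    sprintf("nrows %d", spec$n_lat),
    sprintf("xllcorner %.10f", spec$lon_min),
    sprintf("yllcorner %.10f", spec$lat_min),
    sprintf("cellsize %.10f", spec$resolution),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(vals[rev(seq_len(spec$n_lat)), , drop = FALSE], 1, function(r) {
    r[is.na(r)] <- nodata
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an environmental layer from an ESRI ASCII grid
#'
#' Rows in the file run north to south; the returned grid has latitude
#' ascending. Cells equal to the nodata marker become `NA`.
#'
#' @param path File path.
#' @param variable Variable name to attach to the layer.
#' @param units Unit string to attach.
#' @return An [env_grid()].
#' @export
read_env_layer <- function(path, variable, units = "") {
  if (!file.exists(path)) stop("cannot read layer file: ", path)
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ASCII grid (too short): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line in ", path, ": ", lines[i])
    # non-numeric header values become NA here and fail the is.finite check
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)) || any(!is.finite(unlist(hdr[need])))) {
    stop("missing or non-numeric coordinate metadata in ", path)
  }
  if (hdr$cellsize <= 0) stop("non-positive cell size in ", path)
  n_lat <- as.integer(hdr$nrows); n_lon <- as.integer(hdr$ncols)
  spec <- grid_spec(
    hdr$yllcorner, hdr$yllcorner + n_lat * hdr$cellsize,
    hdr$xllcorner, hdr$xllcorner + n_lon * hdr$cellsize,
    hdr$cellsize
  )
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_lat) stop("row count does not match header in ", path)
  vals <- t(vapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }, numeric(n_lon), USE.NAMES = FALSE))
  vals[vals == hdr$nodata_value] <- NA
  vals <- vals[rev(seq_len(n_lat)), , drop = FALSE]  # file is north-first
  env_grid(spec, variable, vals, units)
}

#' Write an environmental stack as one ASCII grid per layer
#'
#' Files are named `<period>_<variable>.asc` inside `dir`.
#'
#' @param env An [env_stack()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_env_stack <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(env$layers), function(v) {
    p <- file.path(dir, sprintf("%s_%s.asc", env$period_label, v))
    write_env_layer(env$layers[[v]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read an environmental stack written by [write_env_stack()]
#'
#' @param dir Directory containing `<period>_<variable>.asc` files.
#' @param period_label Period to read.
#' @param variables Variables to read; default = all found for the period.
#' @return An [env_stack()].
#' @export
read_env_stack <- function(dir, period_label, variables = NULL) {
  files <- list.files(dir, pattern = sprintf("^%s_.*\\.asc$", period_label),
                      full.names = TRUE)
  if (length(files) == 0) stop("no layers for period ", period_label, " in ", dir)
  vars <- sub(sprintf("^%s_(.*)\\.asc$", period_label), "\\1", basename(files))
  if (!is.null(variables)) {
    keep <- vars %in% variables
    files <- files[keep]; vars <- vars[keep]
    missing <- setdiff(variables, vars)
    if (length(missing)) stop("missing layers: ", paste(missing, collapse = ", "))
  }
  layers <- stats::setNames(
    lapply(seq_along(files), function(i) read_env_layer(files[i], vars[i])),
    vars
  )
  env_stack(period_label, layers)
}

#' Read and write occurrence tables
#'
#' CSV with columns `species, lon, lat, year, source`.
#'
#' @param path CSV file path.
#' @return `read_occurrences`: a data.frame with the five columns.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "year", "source")
  if (!all(need %in% names(df))) {
    stop("occurrence CSV must have columns: ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' @rdname read_occurrences
#' @param records Occurrence data.frame.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Supports `Polygon` geometries (outer ring only); each feature's
#' `properties$name` becomes the polygon label.
#'
#' @param path GeoJSON file path.
#' @return List of polygons, each `list(name =, ring =)` where `ring` is a
#'   closed two-column (lon, lat) matrix.
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon geometries are supported (feature ", i, ")")
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    colnames(ring) <- c("lon", "lat")
    name <- f$properties$name
    if (is.null(name)) name <- sprintf("polygon_%d", i)
    list(name = name, ring = ring)
  })
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' @param polygons List of `list(name =, ring =)` polygons.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    ring <- p$ring
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(i) as.list(unname(ring[i, ])))
    list(
      type = "Feature",
      properties = list(name = p$name),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a suitability map as an ASCII grid
#'
#' @param map A [suitability_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_suitability <- function(map, path) {
  write_env_layer(env_grid(map$spec, "suitability", map$values), path)
}
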