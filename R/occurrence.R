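#' A binary presence grid for one species
#'
#' @param spec A [grid_spec()].
#' @param present Logical `n_lat x n_lon` matrix.
#' @param species Species label.
#' @param n_records Number of records that produced the grid.
#' @return An object of class `presence_grid`.
#' @export
presence_grid <- function(spec, present, species, n_records = sum(present)) {
  present <- as.matrix(present)
  if (!all(dim(present) == c(spec$n_lat, spec$n_lon))) {
    stop("present mask must match the grid spec")
  }
  if (n_records < sum(present)) {
    stop("n_records cannot be smaller than the number of present cells")
  }
  structure(list(spec = spec, present = present, species = species,
                 n_records = as.integer(n_records)),
            class = "presence_grid")
}

#' @export
print.presence_grid <- function(x, ...) {
  cat(sprintf("<presence_grid> %s: %d present cells from %d records\n",
              x$species, sum(x$present), x$n_records))
  invisible(x)
}

#' Quality-filter occurrence records
#'
#' Minimal, individually switchable filters: invalid coordinates (non-finite,
#' `|lat| >= 90`, lon outside `[-180, 180)`), records outside a year window,
#' records on land cells of the reference environment, and exact duplicate
#' (species, grid cell) rows beyond the first. Idempotent.
#'
#' @param records Data.frame with at least `species, lon, lat` (plus `year`
#'   when the year filter is on).
#' @param env Reference [env_stack()] supplying the land mask and grid.
#' @param year_window Length-2 numeric; records outside are dropped.
#' @param rules Named logical vector switching filters `coords`, `years`,
#'   `land`, `dedup`.
#' @return List with `records` (filtered data.frame) and `log` (named drop
#'   counts per rule plus `n_in`/`n_out`).
#' @export
qc_filter <- function(records, env, year_window = c(1971, 2000),
                      rules = c(coords = TRUE, years = TRUE,
                                land = TRUE, dedup = TRUE)) {
  need <- c("species", "lon", "lat")
  if (rules[["years"]]) need <- c(need, "year")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  log <- list(n_in = nrow(records))

  if (rules[["coords"]]) {
    ok <- is.finite(records$lon) & is.finite(records$lat) &
      abs(records$lat) < 90 & records$lon >= -180 & records$lon < 180
    log$dropped_invalid_coords <- sum(!ok)
    records <- records[ok, , drop = FALSE]
  }
  if (rules[["years"]]) {
    ok <- is.finite(records$year) &
      records$year >= year_window[1] & records$year <= year_window[2]
    log$dropped_year_window <- sum(!ok)
    records <- records[ok, , drop = FALSE]
  }
  spec <- env$spec
  idx <- cell_index(records$lon, records$lat, spec)
  if (rules[["land"]]) {
    sea <- sea_mask(env)
    on_grid <- !is.na(idx$row)
    # records off the reference grid cannot be classified; keep them
    on_land <- rep(FALSE, nrow(records))
    on_land[on_grid] <- !sea[cbind(idx$row[on_grid], idx$col[on_grid])]
    log$dropped_on_land <- sum(on_land)
    records <- records[!on_land, , drop = FALSE]
    idx <- cell_index(records$lon, records$lat, spec)
  }
  if (rules[["dedup"]]) {
    key <- paste(records$species, idx$row, idx$col, sep = "\r")
    dup <- duplicated(key)
    log$dropped_duplicates <- sum(dup)
    records <- records[!dup, , drop = FALSE]
  }
  log$n_out <- nrow(records)
  rownames(records) <- NULL
  list(records = records, log = log)
}

#' Aggregate occurrence records to a binary presence grid
#'
#' A cell is present iff at least one record falls inside it; cells are
#' half-open boxes `[edge, edge + res)` so edge records belong to the cell
#' whose lower edge they match. Records outside the grid are dropped with a
#' warning.
#'
#' @param records QC-filtered occurrence data.frame (single species, or pass
#'   `species` to subset).
#' @param spec Target [grid_spec()].
#' @param species Species to aggregate; required when `records` holds more
#'   than one.
#' @return A [presence_grid()].
#' @export
aggregate_to_grid <- function(records, spec, species = NULL) {
  if (is.null(species)) {
    sp <- unique(records$species)
    if (length(sp) > 1) stop("records hold several species; pass `species`")
    species <- if (length(sp) == 1) sp else ""
  } else {
    records <- records[records$species == species, , drop = FALSE]
  }
  present <- matrix(FALSE, spec$n_lat, spec$n_lon)
  n_records <- 0L
  if (nrow(records) > 0) {
    idx <- cell_index(records$lon, records$lat, spec)
    off <- is.na(idx$row)
    if (any(off)) {
      warning(sum(off), " record(s) outside the grid were dropped")
    }
    n_records <- sum(!off)
    if (n_records > 0) {
      present[cbind(idx$row[!off], idx$col[!off])] <- TRUE
    }
  }
  presence_grid(spec, present, species, n_records)
}

#' Split presence cells into training and test sets
#'
#' Cell-level partition (spatial duplicates cannot leak across the split):
#' the training grid gets `round(train_fraction * n)` randomly chosen present
#' cells and the test grid the rest. Both halves must be non-empty.
#'
#' @param presence A [presence_grid()].
#' @param train_fraction Proportion of present cells used for training
#'   (default 0.75).
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` [presence_grid()]s.
#' @export
split_train_test <- function(presence, train_fraction = 0.75, seed = 1) {
  cells <- which(presence$present)
  n <- length(cells)
  if (n < 4) stop("too few present cells to split (need >= 4)")
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("train_fraction leaves an empty train or test set")
  }
  train_cells <- with_seed(seed, sample(cells, n_train))
  train <- matrix(FALSE, presence$spec$n_lat, presence$spec$n_lon)
  train[train_cells] <- TRUE
  test <- presence$present & !train
  list(
    train = presence_grid(presence$spec, train, presence$species, n_train),
    test = presence_grid(presence$spec, test, presence$species, n - n_train)
  )
}
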