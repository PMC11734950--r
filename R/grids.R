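#' Regular spatial grids and per-cell surfaces
#'
#' A `grid_spec` is a regular rectangular grid over a lon/lat (degree mode) or
#' planar km (km mode) extent. Cells are half-open intervals
#' `[west, east) x [south, north)`; points lying exactly on the outermost
#' east/north boundary are assigned to the last cell so that the extent is
#' fully tiled. Cell ids run 1..ncell row-major from the south-west corner
#' (row 1 is the southernmost row, column 1 the westernmost column).
#'
#' @param lon_min,lon_max,lat_min,lat_max extent, in degrees (degree mode) or
#'   km (km mode).
#' @param resolution cell size in the extent's units; a single number
#'   (square cells).
#' @param mode `"degree"` (default) or `"km"`. The mode only labels the units;
#'   grid arithmetic is identical. Grids in different modes cannot be
#'   regridded into each other.
#' @param mask optional logical vector, length ncell, `TRUE` for cells in the
#'   study domain (ocean). Default all `TRUE`.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- build_grid(-70, -50, 40, 60, resolution = 1)
#' g$ncell
#' @export
build_grid <- function(lon_min, lon_max, lat_min, lat_max, resolution,
                       mode = c("degree", "km"), mask = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("`resolution` must be a single positive number")
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("degenerate extent: require lon_max > lon_min and lat_max > lat_min")
  if ((lon_max - lon_min) < resolution || (lat_max - lat_min) < resolution)
    stop("extent smaller than one cell at this resolution")
  ncol <- round((lon_max - lon_min) / resolution)
  nrow <- round((lat_max - lat_min) / resolution)
  if (abs(ncol * resolution - (lon_max - lon_min)) > 1e-8 * resolution ||
      abs(nrow * resolution - (lat_max - lat_min)) > 1e-8 * resolution)
    stop("extent must be an integer multiple of the resolution in both axes")
  ncell <- nrow * ncol
  if (is.null(mask)) mask <- rep(TRUE, ncell)
  if (!is.logical(mask) || length(mask) != ncell)
    stop("`mask` must be a logical vector with one entry per cell")
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         resolution = resolution, mode = mode,
         nrow = nrow, ncol = ncol, ncell = ncell, mask = mask),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (%d total), res %g %s\n",
              x$nrow, x$ncol, x$ncell, x$resolution,
              if (x$mode == "degree") "deg" else "km"))
  cat(sprintf("  extent: [%g, %g] x [%g, %g]; %d masked-in cells\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max, sum(x$mask)))
  invisible(x)
}

#' Cell index of points on a grid
#'
#' Maps coordinates to 1-based cell ids using the half-open cell convention;
#' the outermost east/north boundary belongs to the last cell. Points outside
#' the extent map to `NA`.
#'
#' @param grid a [build_grid()] grid.
#' @param lon,lat coordinate vectors of equal length.
#' @return integer vector of cell ids (`NA` = out of domain).
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  col <- floor((lon - grid$lon_min) / grid$resolution) + 1L
  row <- floor((lat - grid$lat_min) / grid$resolution) + 1L
  # outermost east/north boundary belongs to the last cell
  col[lon == grid$lon_max] <- grid$ncol
  row[lat == grid$lat_max] <- grid$nrow
  out <- (row - 1L) * grid$ncol + col
  bad <- col < 1L | col > grid$ncol | row < 1L | row > grid$nrow |
    is.na(lon) | is.na(lat)
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Cell centroids
#'
#' @param grid a [build_grid()] grid.
#' @param cells cell ids; default all cells.
#' @return data.frame with `cell`, `lon`, `lat` (centroid coordinates).
#' @export
cell_centroids <- function(grid, cells = seq_len(grid$ncell)) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- (cells - 1L) %% grid$ncol + 1L
  row <- (cells - 1L) %/% grid$ncol + 1L
  data.frame(cell = cells,
             lon = grid$lon_min + (col - 0.5) * grid$resolution,
             lat = grid$lat_min + (row - 0.5) * grid$resolution)
}

#' Per-cell numeric surface
#'
#' A `surface` couples a grid with one numeric value per cell (counts, vessel
#' hours, habitat suitability, risk, ...). Masked-out cells carry `NA`.
#'
#' @param grid a [build_grid()] grid.
#' @param values numeric vector, length `grid$ncell`.
#' @param period optional period label (e.g. `"present"`).
#' @param species optional species label.
#' @param units optional unit string.
#' @return an object of class `surface`.
#' @export
surface <- function(grid, values, period = NULL, species = NULL, units = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) != grid$ncell)
    stop("`values` length must equal the grid cell count")
  if (any(!is.finite(values[grid$mask])))
    stop("non-finite values on masked-in cells")
  values[!grid$mask] <- NA_real_
  structure(list(grid = grid, values = as.numeric(values),
                 period = period, species = species, units = units),
            class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  v <- x$values[x$grid$mask]
  cat(sprintf("surface on %d x %d grid%s%s: range [%g, %g], sum %g\n",
              x$grid$nrow, x$grid$ncol,
              if (!is.null(x$species)) paste0(", species ", x$species) else "",
              if (!is.null(x$period)) paste0(", period ", x$period) else "",
              min(v), max(v), sum(v)))
  invisible(x)
}

#' Surface values on masked-in cells
#' @param x a [surface()].
#' @return numeric vector over masked-in cells, in cell-id order.
#' @export
surface_values <- function(x) {
  stopifnot(inherits(x, "surface"))
  x$values[x$grid$mask]
}

# controlled species vocabulary (six NWA baleen whales + catch-all)
WHALE_SPECIES <- c("blue", "fin", "humpback", "minke", "na_right", "sei")

#' Normalize species labels to the controlled vocabulary
#'
#' Labels outside the six-species vocabulary (blue, fin, humpback, minke,
#' na_right, sei) map to `"unidentified"` with a warning.
#'
#' @param species character vector.
#' @return character vector over the controlled vocabulary.
#' @export
normalize_species <- function(species) {
  species <- tolower(trimws(as.character(species)))
  known <- species %in% c(WHALE_SPECIES, "unidentified")
  if (any(!known)) {
    warning(sprintf("%d species label(s) outside the controlled vocabulary mapped to 'unidentified': %s",
                    sum(!known), paste(unique(species[!known]), collapse = ", ")))
    species[!known] <- "unidentified"
  }
  species
}

#' Aggregate point records onto a grid
#'
#' Bins point records into grid cells and reduces per cell, either counting
#' points or summing a numeric attribute (e.g. vessel hours). Points outside
#' the extent are excluded and reported via the `"excluded"` attribute.
#'
#' @param points data.frame with `lon` and `lat` columns (plus the attribute
#'   column when `reducer = "sum"`).
#' @param grid a [build_grid()] grid.
#' @param reducer `"count"` or `"sum"`.
#' @param attribute column name to sum when `reducer = "sum"`.
#' @param ... passed to [surface()] (period/species labels).
#' @return a [surface()] of per-cell totals, with attribute `"excluded"`
#'   giving the number of out-of-domain points.
#' @export
aggregate_points <- function(points, grid, reducer = c("count", "sum"),
                             attribute = NULL, ...) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(grid, "grid_spec"))
  if (!all(c("lon", "lat") %in% names(points)))
    stop("`points` must have `lon` and `lat` columns")
  if (reducer == "sum") {
    if (is.null(attribute) || !attribute %in% names(points))
      stop("`attribute` must name a column of `points` when reducer = 'sum'")
  }
  if (nrow(points) == 0) {
    warning("empty point input: returning an all-zero surface")
    out <- surface(grid, rep(0, grid$ncell), ...)
    attr(out, "excluded") <- 0L
    return(out)
  }
  cells <- cell_index(grid, points$lon, points$lat)
  inside <- !is.na(cells)
  vals <- numeric(grid$ncell)
  if (any(inside)) {
    w <- if (reducer == "count") rep(1, sum(inside)) else
      as.numeric(points[[attribute]][inside])
    agg <- tapply(w, cells[inside], sum)
    vals[as.integer(names(agg))] <- agg
  }
  out <- surface(grid, vals, ...)
  attr(out, "excluded") <- sum(!inside)
  out
}

#' Binarize a count surface to presence/absence
#'
#' Every cell with one or more records becomes a presence (1); empty cells
#' stay 0. This is the spatial-filtering step that prevents heavily resighted
#' cells from dominating a presence-only model.
#'
#' @param count_surface a [surface()] of non-negative counts.
#' @return a 0/1 [surface()].
#' @export
presence_binarize <- function(count_surface) {
  stopifnot(inherits(count_surface, "surface"))
  v <- count_surface$values
  if (any(v < 0, na.rm = TRUE)) stop("negative counts are not allowed")
  out <- count_surface
  out$values <- ifelse(is.na(v), NA_real_, as.numeric(v >= 1))
  out
}

#' Regrid a fine surface onto a coarser grid by centroid-mean
#'
#' Each coarse cell takes the mean of the fine-cell values whose centroids
#' fall inside it (e.g. mean ensemble habitat suitability per 1-degree cell).
#' Coarse cells receiving no fine centroid are masked out.
#'
#' @param fine a [surface()] on the fine grid.
#' @param coarse a [build_grid()] grid in the same mode.
#' @return a [surface()] on `coarse`.
#' @export
regrid_mean <- function(fine, coarse) {
  stopifnot(inherits(fine, "surface"), inherits(coarse, "grid_spec"))
  fg <- fine$grid
  if (fg$mode != coarse$mode)
    stop("cannot regrid between degree-mode and km-mode grids")
  cen <- cell_centroids(fg)
  tgt <- cell_index(coarse, cen$lon, cen$lat)
  ok <- !is.na(tgt) & !is.na(fine$values)
  if (!any(ok)) stop("fine and coarse grids have disjoint extents")
  agg <- tapply(fine$values[ok], tgt[ok], mean)
  vals <- rep(NA_real_, coarse$ncell)
  vals[as.integer(names(agg))] <- agg
  newmask <- coarse$mask & !is.na(vals)
  g2 <- coarse
  g2$mask <- newmask
  vals[!newmask] <- NA_real_
  out <- surface(g2, ifelse(newmask, vals, 0), period = fine$period,
                 species = fine$species, units = fine$units)
  out$values[!newmask] <- NA_real_
  out
}

#' Read point records from CSV
#'
#' Expects at least `lon`, `lat`, `species`, `date` columns; extra columns
#' (incident condition, vessel hours, ...) are kept. Species labels are
#' normalized to the controlled vocabulary.
#'
#' @param path CSV file path.
#' @return data.frame of point records.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "species", "date")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("point CSV missing required column(s): ", paste(miss, collapse = ", "))
  df$species <- normalize_species(df$species)
  df
}

#' Write / read a surface as long-format CSV
#'
#' Columns `cell_id`, `lon`, `lat`, `value` (centroid coordinates, one row per
#' cell, masked-out cells with empty value). The CSV round-trips values
#' bit-stably via full-precision formatting.
#'
#' @param x a [surface()].
#' @param path file path.
#' @return `write_surface_csv` returns `path` invisibly; `read_surface_csv`
#'   returns a [surface()] on `grid`.
#' @export
write_surface_csv <- function(x, path) {
  stopifnot(inherits(x, "surface"))
  cen <- cell_centroids(x$grid)
  df <- data.frame(cell_id = cen$cell,
                   lon = sprintf("%.10g", cen$lon),
                   lat = sprintf("%.10g", cen$lat),
                   value = ifelse(is.na(x$values), "",
                                  sprintf("%.17g", x$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @param grid the grid the surface lives on.
#' @export
read_surface_csv <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "value")
  if (!all(need %in% names(df)))
    stop("surface CSV missing required column(s)")
  vals <- rep(NA_real_, grid$ncell)
  vals[df$cell_id] <- suppressWarnings(as.numeric(df$value))
  g <- grid
  g$mask <- grid$mask & !is.na(vals)
  vals[!g$mask] <- NA_real_
  out <- surface(g, ifelse(g$mask, vals, 0))
  out$values[!g$mask] <- NA_real_
  out
}
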