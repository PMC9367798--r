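#' Rectangular raster grid
#'
#' Lightweight in-memory raster: a numeric matrix plus cell size, origin and
#' a nodata sentinel. Row 1 is the top of the map; cells are addressed
#' (row, col). Nodata cells are stored as `NA` and written out using the
#' `nodata` sentinel. Area accounting everywhere in the package is
#' `cells * cell_size^2`, reported in km2 (the 30 m default gives
#' 900 m2 per cell).
#'
#' @param values numeric matrix (rows x cols); `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, map coordinates (x, y) of the lower-left
#'   corner of the grid.
#' @param nodata sentinel value used when the grid is written to disk.
#' @return an object of class `les_raster`.
#' @export
les_raster <- function(values, cell_size = 30, origin = c(0, 0),
                       nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) >= 1, ncol(values) >= 1,
            is.numeric(cell_size), length(cell_size) == 1, cell_size > 0,
            length(origin) == 2)
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values in raster (use NA for nodata)")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), nodata = as.numeric(nodata)),
            class = "les_raster")
}

#' Categorical land-use map
#'
#' A [les_raster] whose cells hold integer class codes with a legend. The
#' default legend is the six-class scheme used throughout the package:
#' 1 farmland, 2 woodland, 3 grassland, 4 water, 5 construction, 6 unused.
#'
#' @param values integer matrix of class codes (`NA` = nodata).
#' @param legend named character vector mapping code to class name.
#' @inheritParams les_raster
#' @return an object of class `c("les_landuse", "les_raster")`.
#' @export
les_landuse <- function(values, legend = landuse_legend(), cell_size = 30,
                        origin = c(0, 0), nodata = -9999) {
  r <- les_raster(values, cell_size, origin, nodata)
  v <- r$values[!is.na(r$values)]
  if (length(v) && any(v != round(v)))
    stop("land-use map must hold integer class codes")
  if (length(legend) > 6) stop("legend has more than 6 entries")
  codes <- as.integer(names(legend))
  if (length(v) && !all(v %in% codes))
    stop("cell codes outside legend: ",
         paste(setdiff(unique(v), codes), collapse = ", "))
  r$legend <- legend
  class(r) <- c("les_landuse", "les_raster")
  r
}

#' @rdname les_landuse
#' @export
landuse_legend <- function() {
  c(`1` = "farmland", `2` = "woodland", `3` = "grassland",
    `4` = "water", `5` = "construction", `6` = "unused")
}

#' @export
print.les_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<%s> %d x %d cells, %g m cells, origin (%g, %g)\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  if (inherits(x, "les_landuse")) {
    tab <- table(factor(v, levels = names(x$legend), labels = x$legend))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  } else if (length(v)) {
    cat(sprintf("  range [%g, %g], nodata cells: %d\n", min(v), max(v),
                sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
plot.les_raster <- function(x, main = NULL, ...) {
  v <- x$values
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), axes = FALSE,
                  main = main %||% class(x)[1], useRaster = TRUE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a raster from an ESRI ASCII grid file
#'
#' @param path path to an ESRI ASCII grid (`.asc`).
#' @param kind `"continuous"` or `"categorical"`; categorical grids must
#'   hold integer codes and are returned as [les_landuse] when the codes
#'   fit the six-class legend.
#' @param legend legend used in categorical mode.
#' @return a [les_raster] (or [les_landuse] in categorical mode).
#' @export
read_raster <- function(path, kind = c("continuous", "categorical"),
                        legend = landuse_legend()) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (kind == "categorical") {
    if (any(m != round(m), na.rm = TRUE))
      stop("non-integer values in categorical raster: ", path)
    les_landuse(m, legend = legend, cell_size = hdr$cellsize,
                origin = c(hdr$xllcorner, hdr$yllcorner), nodata = nodata)
  } else {
    les_raster(m, cell_size = hdr$cellsize,
               origin = c(hdr$xllcorner, hdr$yllcorner), nodata = nodata)
  }
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param x a [les_raster].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "les_raster"))
  v <- x$values
  v[is.na(v)] <- x$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", x$origin[1]),
           sprintf("yllcorner %.10g", x$origin[2]),
           sprintf("cellsize %.10g", x$cell_size),
           sprintf("NODATA_value %.10g", x$nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Check that rasters share the same grid
#'
#' True iff all grids agree in rows, cols, cell size and origin.
#'
#' @param grids a list of [les_raster] objects (non-empty).
#' @return logical scalar.
#' @export
check_aligned <- function(grids) {
  stopifnot(is.list(grids), length(grids) >= 1)
  ref <- grids[[1]]
  all(vapply(grids, function(g) {
    identical(dim(g$values), dim(ref$values)) &&
      isTRUE(all.equal(g$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(g$origin, ref$origin))
  }, logical(1)))
}

.assert_aligned <- function(...) {
  if (!check_aligned(list(...))) stop("rasters are not aligned")
}

#' Euclidean distance to target cells
#'
#' Exact centre-to-centre Euclidean distance (in map units) from every cell
#' to the nearest target cell; target cells get 0. Nodata cells are
#' propagated as nodata and never act as targets.
#'
#' @param targets a [les_raster] with nonzero values (or `TRUE`) at target
#'   cells, or a logical/numeric matrix.
#' @param cell_size used when `targets` is a bare matrix.
#' @return a [les_raster] of distances in metres.
#' @export
euclidean_distance <- function(targets, cell_size = 30) {
  if (inherits(targets, "les_raster")) {
    m <- targets$values
    cs <- targets$cell_size
    org <- targets$origin
  } else {
    m <- as.matrix(targets)
    cs <- cell_size
    org <- c(0, 0)
  }
  tgt <- !is.na(m) & m != 0
  if (!any(tgt)) stop("no target cells")
  # distmap() gives the exact Euclidean distance to the nearest 0 pixel
  d <- EBImage::distmap(matrix(as.numeric(!tgt), nrow(m), ncol(m))) * cs
  d <- matrix(as.numeric(d), nrow(m), ncol(m))
  d[is.na(m)] <- NA
  les_raster(d, cell_size = cs, origin = org)
}

#' Min-max rescale a raster to [0, 1]
#'
#' Linear membership rescaling over the non-nodata cells: `increasing`
#' maps the minimum to 0 and maximum to 1, `decreasing` the reverse.
#'
#' @param grid a [les_raster] or numeric matrix with >= 2 distinct values.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return same type as `grid`, values in [0, 1], nodata preserved.
#' @export
minmax_rescale <- function(grid, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  m <- if (inherits(grid, "les_raster")) grid$values else as.matrix(grid)
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) stop("constant grid cannot be rescaled")
  out <- (m - rng[1]) / diff(rng)
  if (direction == "decreasing") out <- 1 - out
  if (inherits(grid, "les_raster")) {
    grid$values <- out
    class(grid) <- "les_raster"   # result is continuous
    grid$legend <- NULL
    grid
  } else out
}

#' Per-class area in km2
#'
#' @param landuse a [les_landuse].
#' @return named numeric vector of km2 per legend class.
#' @export
class_areas <- function(landuse) {
  stopifnot(inherits(landuse, "les_landuse"))
  n <- table(factor(landuse$values[!is.na(landuse$values)],
                    levels = names(landuse$legend)))
  a <- as.numeric(n) * landuse$cell_size^2 / 1e6
  names(a) <- unname(landuse$legend)
  a
}
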