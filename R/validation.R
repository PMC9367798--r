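#' Cross-tabulation of two land-use maps
#'
#' Confusion matrix of co-occurring class pairs over cells that are
#' non-nodata in both maps.
#'
#' @param a,b aligned [les_landuse] maps with a shared legend.
#' @return integer matrix, rows = classes of `a`, columns = classes of
#'   `b`.
#' @export
crosstab <- function(a, b) {
  .assert_aligned(a, b)
  if (!identical(a$legend, b$legend)) stop("legend mismatch")
  codes <- names(a$legend)
  ok <- !is.na(a$values) & !is.na(b$values)
  m <- table(factor(a$values[ok], levels = codes),
             factor(b$values[ok], levels = codes))
  matrix(as.integer(m), nrow(m), dimnames = dimnames(m))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement over the full-map census:
#' p0 = trace/total, pe = sum of (row total x column total)/total^2,
#' kappa = (p0 - pe)/(1 - pe).
#'
#' @param matrix square confusion matrix of counts.
#' @return object of class `agreement_stats` with `p0`, `pe`, `kappa`,
#'   `matrix`, `n`.
#' @export
kappa_stats <- function(matrix) {
  n <- sum(matrix)
  stopifnot(n > 0, nrow(matrix) == ncol(matrix))
  p0 <- sum(diag(matrix)) / n
  pe <- sum(rowSums(matrix) * colSums(matrix)) / n^2
  if (pe >= 1) stop("degenerate single-class comparison (pe = 1)")
  structure(list(p0 = p0, pe = pe, kappa = (p0 - pe) / (1 - pe),
                 matrix = matrix, n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("overall agreement %.4f, expected %.4f, kappa %.4f (n = %d)\n",
              x$p0, x$pe, x$kappa, x$n))
  invisible(x)
}

#' Land-use change accounting table
#'
#' Per class: area at the base date, per-scenario areas at the later date,
#' difference (km2) and percentage change relative to the base. Accepts
#' maps (areas from cell counts) or already-computed areas.
#'
#' @param base base-date [les_landuse] or named vector of km2 per class.
#' @param ... later-date maps or area vectors, named by scenario.
#' @return data frame: `class`, `area_<base>`, then per scenario
#'   `area_*`, `diff_*` (km2) and `pct_*` (%).
#' @export
change_table <- function(base, ...) {
  as_area <- function(x) if (inherits(x, "les_landuse")) class_areas(x) else x
  a0 <- as_area(base)
  scen <- lapply(list(...), as_area)
  stopifnot(length(scen) >= 1, !is.null(names(scen)))
  out <- data.frame(class = names(a0), area_base = unname(a0))
  for (s in names(scen)) {
    a1 <- scen[[s]][names(a0)]
    out[[paste0("area_", s)]] <- unname(a1)
    out[[paste0("diff_", s)]] <- unname(a1 - a0)
    out[[paste0("pct_", s)]] <- unname(ifelse(a0 > 0,
                                              100 * (a1 - a0) / a0, NA))
  }
  out
}

#' Land-use areas within ecological zones
#'
#' Per (class, zone) area in km2 plus the row proportion: the percentage
#' of each class's total area that falls in each zone (rows sum to 100).
#'
#' @param landuse a [les_landuse].
#' @param zones an [eco_zoning] on the same grid (or an aligned zone-code
#'   matrix).
#' @return list: `area` (class x zone km2 matrix with a `total` column),
#'   `proportion` (row percentages).
#' @export
zone_landuse_table <- function(landuse, zones) {
  zv <- if (inherits(zones, "eco_zoning")) {
    z <- zones$zones
    if (inherits(z, "les_raster")) z$values else z
  } else zones
  v <- landuse$values
  stopifnot(identical(dim(zv), dim(v)))
  ok <- !is.na(v) & !is.na(zv)
  cnt <- table(factor(v[ok], levels = names(landuse$legend)),
               factor(zv[ok], levels = 1:4))
  area <- matrix(as.numeric(cnt), nrow(cnt)) * landuse$cell_size^2 / 1e6
  dimnames(area) <- list(unname(landuse$legend), names(.zone_codes))
  prop <- 100 * area / rowSums(area)
  list(area = cbind(area, total = rowSums(area)), proportion = prop)
}

#' Row proportions for a printed zone-area table
#'
#' Convenience for accounting checks on already-tabulated per-zone areas.
#'
#' @param areas named or unnamed numeric vector of per-zone areas for one
#'   class.
#' @return percentages of the class total per zone.
#' @export
zone_proportions <- function(areas) {
  stopifnot(all(areas >= 0), sum(areas) > 0)
  100 * areas / sum(areas)
}
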