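#' Fisher-Jenks natural breaks
#'
#' Exact optimal 1-D partition into `k` classes minimizing the within-class
#' sum of squared deviations, by dynamic programming over the sorted
#' values. Returned breakpoints are the upper value of each of the lower
#' k-1 classes; a value v belongs to the lowest class whose breakpoint is
#' >= v.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of classes (>= 2).
#' @return numeric vector of k-1 strictly increasing breakpoints.
#' @export
jenks_breaks <- function(values, k) {
  values <- values[!is.na(values)]
  stopifnot(k >= 2)
  if (length(unique(values)) < k)
    stop("need at least k distinct values")
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ssd of x[i..j], 1-based inclusive
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[c, j]: min cost of splitting x[1..j] into c classes; B: last class start
  D <- matrix(Inf, k, n)
  B <- matrix(NA_integer_, k, n)
  for (j in 1:n) { D[1, j] <- ssd(1, j); B[1, j] <- 1L }
  for (c in 2:k) {
    for (j in c:n) {
      best <- Inf; bi <- NA_integer_
      for (i in c:j) {
        cost <- D[c - 1, i - 1] + ssd(i, j)
        if (cost < best - 1e-12) { best <- cost; bi <- i }
      }
      D[c, j] <- best; B[c, j] <- bi
    }
  }
  # backtrack class boundaries
  ends <- integer(k)
  j <- n
  for (c in k:1) { ends[c] <- j; j <- B[c, j] - 1L }
  breaks <- x[ends[-k]]
  if (any(diff(breaks) <= 0)) stop("degenerate breaks (duplicate values)")
  breaks
}

.zone_codes <- c(UDZ = 1, EOZ = 2, EBZ = 3, ECZ = 4)

#' Classify security indices into ecological zones
#'
#' Four-zone partition by three increasing breakpoints on the adjusted
#' index: the top class (ecological core zone, ECZ) is open below
#' (value > top break); each lower class takes values above its lower
#' break, up to and including its upper break; everything at or below the
#' bottom break is urban development zone (UDZ). Zones in between are the
#' ecological buffer (EBZ) and optimization (EOZ) zones.
#'
#' @param x numeric vector of adjusted indices, or a [les_raster] of them.
#' @param breaks 3 strictly increasing breakpoints (e.g. from
#'   [jenks_breaks()] with k = 4).
#' @param raw optional raw (unadjusted) indices parallel to `x`, used to
#'   report per-zone mean raw index and raw-unit thresholds.
#' @param cell_size cell size for area accounting when `x` is a vector;
#'   each element then counts as one cell.
#' @return object of class `eco_zoning`: zone codes (1 UDZ .. 4 ECZ),
#'   per-zone area (km2), share (%), mean raw index and raw thresholds.
#' @export
classify_zones <- function(x, breaks, raw = NULL, cell_size = 1000) {
  stopifnot(length(breaks) == 3, all(diff(breaks) > 0))
  is_r <- inherits(x, "les_raster")
  v <- if (is_r) x$values else x
  code <- findInterval(as.numeric(v), breaks, left.open = TRUE) + 1L
  code[is.na(as.numeric(v))] <- NA_integer_
  dim(code) <- dim(v)
  cs <- if (is_r) x$cell_size else cell_size
  cnt <- tabulate(code, nbins = 4)
  areas <- cnt * cs^2 / 1e6
  names(areas) <- names(.zone_codes)
  mean_raw <- raw_thresh <- rep(NA_real_, 4)
  if (!is.null(raw)) {
    rv <- as.numeric(raw)
    for (z in 1:4) {
      if (cnt[z] > 0) {
        mean_raw[z] <- mean(rv[which(code == z)], na.rm = TRUE)
        raw_thresh[z] <- min(rv[which(code == z)], na.rm = TRUE)
      }
    }
  }
  zr <- if (is_r) { y <- x; y$values <- code + 0; y$legend <- NULL
                    class(y) <- "les_raster"; y } else code
  structure(list(zones = zr, breaks = breaks, area_km2 = areas,
                 share_pct = zone_shares(areas), mean_raw = mean_raw,
                 raw_threshold = raw_thresh, codes = .zone_codes),
            class = "eco_zoning")
}

#' Zone area shares
#'
#' @param areas non-negative per-zone areas (km2), total > 0.
#' @return percentages summing to 100.
#' @export
zone_shares <- function(areas) {
  stopifnot(all(areas >= 0), sum(areas) > 0)
  100 * areas / sum(areas)
}

#' @export
print.eco_zoning <- function(x, ...) {
  cat("<eco_zoning> breaks:", paste(signif(x$breaks, 4), collapse = ", "),
      "\n")
  df <- data.frame(zone = names(x$area_km2),
                   area_km2 = round(x$area_km2, 2),
                   share_pct = round(x$share_pct, 2),
                   mean_raw = round(x$mean_raw, 3))
  print(df[order(-.zone_codes[df$zone]), ], row.names = FALSE)
  invisible(x)
}

#' Zone membership mask
#'
#' @param zoning an [eco_zoning] built from a raster.
#' @param zone zone name (`"ECZ"`, `"EBZ"`, `"EOZ"`, `"UDZ"`).
#' @return logical matrix, `TRUE` inside the zone.
#' @export
zone_mask <- function(zoning, zone = "ECZ") {
  stopifnot(inherits(zoning, "eco_zoning"))
  code <- .zone_codes[[zone]]
  v <- if (inherits(zoning$zones, "les_raster")) zoning$zones$values
       else zoning$zones
  !is.na(v) & v == code
}
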