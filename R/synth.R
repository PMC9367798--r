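#' Synthetic-world specification
#'
#' Parameters for the seeded generator: grid size, class budget
#' (proportions of the six classes), patchiness, per-decade transition
#' intensities (`drift`), driver-field noise, and the indicator model.
#' Defaults sketch a rapidly urbanizing subtropical landscape: woodland
#' dominated with a substantial farmland belt, an established built-up
#' core, and a decade of farmland-to-construction conversion.
#'
#' @param rows,cols grid dimensions.
#' @param cell_size cell edge (m).
#' @param proportions named class budget summing to 1.
#' @param patch_radius mean patch radius in cells (sets nuclei density).
#' @param drift 6x6 matrix of per-decade conversion fractions (row =
#'   source class); default: urbanization out of farmland/grassland with
#'   minor afforestation.
#' @param pop_scale,pop_noise_sd population surface peak and noise sd.
#' @param indicator_noise_sd sd of the noise on landscape-coupled
#'   indicators (percent points).
#' @param units_dim number of indicator grid units per side.
#' @param seed mandatory integer seed; all generator randomness flows from
#'   it through fixed per-component substreams.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(rows = 200, cols = 200, cell_size = 30,
                       proportions = c(farmland = 0.28, woodland = 0.40,
                                       grassland = 0.04, water = 0.08,
                                       construction = 0.18, unused = 0.02),
                       patch_radius = 6,
                       drift = NULL,
                       pop_scale = 5000, pop_noise_sd = 250,
                       indicator_noise_sd = 2,
                       units_dim = 20,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(abs(sum(proportions) - 1) < 1e-9, length(proportions) == 6)
  if (is.null(drift)) {
    drift <- matrix(0, 6, 6, dimnames = list(1:6, 1:6))
    drift["1", "5"] <- 0.10  # farmland -> construction
    drift["1", "2"] <- 0.02  # farmland -> woodland
    drift["2", "5"] <- 0.02  # woodland -> construction
    drift["2", "1"] <- 0.01  # woodland -> farmland
    drift["3", "5"] <- 0.04  # grassland -> construction
    drift["3", "2"] <- 0.03  # grassland -> woodland
    drift["6", "5"] <- 0.05  # unused -> construction
  }
  stopifnot(all(drift >= 0), all(rowSums(drift) < 1))
  structure(list(rows = rows, cols = cols, cell_size = cell_size,
                 proportions = proportions, patch_radius = patch_radius,
                 drift = drift, pop_scale = pop_scale,
                 pop_noise_sd = pop_noise_sd,
                 indicator_noise_sd = indicator_noise_sd,
                 units_dim = units_dim, seed = as.integer(seed)),
            class = "synth_spec")
}

# count of same-class neighbors within `window`, reusing the CA box filter
.adjacency <- function(state, class, window = 3)
  neighborhood_factor(state, class, window) > 0

#' Generate a synthetic land-use map pair
#'
#' t0 grows contiguous class patches from seeded random nuclei (iterative
#' dilation with per-class budget caps) until the class budget is met;
#' t1 applies the spec's drift intensities, converting for each (from, to)
#' pair `round(drift * n_from)` cells chosen preferentially at class
#' boundaries (high neighborhood fraction of the gaining class), so change
#' is spatially autocorrelated. Deterministic given the spec seed.
#'
#' @param spec a [synth_spec].
#' @return list of two aligned [les_landuse] maps, `t0` and `t1`.
#' @export
synth_landscape <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  nr <- spec$rows; nc <- spec$cols
  ncell <- nr * nc
  budget <- lr_round(spec$proportions * ncell, ncell)
  state <- matrix(0L, nr, nc)
  # nuclei per class, proportional to budget over mean patch area
  for (k in 1:6) {
    nn <- max(1L, round(budget[k] / (pi * spec$patch_radius^2)))
    free <- which(state == 0L)
    pts <- sample(free, min(nn, length(free)))
    state[pts] <- k
  }
  deficit <- budget - tabulate(state, 6)
  # budget-capped multi-source dilation; a deficit class whose patches got
  # enclosed is re-seeded in remaining free space so budgets are met
  repeat {
    grew <- FALSE
    for (k in order(-deficit)) {
      if (deficit[k] <= 0) next
      cand <- which(.adjacency(state, k) & state == 0L)
      if (!length(cand)) {
        free <- which(state == 0L)
        if (!length(free)) next
        cand <- sample(free,
                       min(length(free),
                           max(1L, ceiling(deficit[k] /
                                             (pi * spec$patch_radius^2)))))
      }
      pick <- if (length(cand) > deficit[k])
        sample(cand, deficit[k]) else cand
      state[pick] <- k
      deficit[k] <- deficit[k] - length(pick)
      grew <- TRUE
    }
    if (!any(state == 0L) || !grew) break
  }
  if (any(state == 0L)) state[state == 0L] <- which.max(deficit)
  t0 <- les_landuse(state, cell_size = spec$cell_size)
  # ---- drift to t1, boundary-preferential ----
  s1 <- state
  pairs <- which(spec$drift > 0, arr.ind = TRUE)
  pairs <- pairs[order(-spec$drift[pairs]), , drop = FALSE]
  n0 <- tabulate(state, 6)
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]; v <- pairs[r, 2]
    n <- round(spec$drift[u, v] * n0[u])
    if (n == 0) next
    cand <- which(s1 == u & state == u)  # not already converted
    if (!length(cand)) next
    h <- neighborhood_factor(s1, v, 5)
    score <- h[cand] + stats::runif(length(cand), 0, 0.05)
    sel <- cand[order(-score)][seq_len(min(n, length(cand)))]
    s1[sel] <- v
  }
  t1 <- les_landuse(s1, cell_size = spec$cell_size)
  list(t0 = t0, t1 = t1)
}

# bilinear upsample of a coarse matrix onto an nr x nc grid
.smooth_field <- function(coarse, nr, nc) {
  ry <- seq(1, nrow(coarse), length.out = nr)
  rx <- seq(1, ncol(coarse), length.out = nc)
  rows <- t(apply(coarse, 1, function(r)
    stats::approx(seq_along(r), r, xout = rx)$y))
  apply(rows, 2, function(cl)
    stats::approx(seq_along(cl), cl, xout = ry)$y)
}

#' Generate an aligned driver stack for a synthetic landscape
#'
#' Synthesizes river/road/town/settlement target masks, derives the four
#' distance surfaces with the exact distance transform, builds population
#' as an exponentially decaying function of distance-to-town plus noise,
#' and elevation/slope as smooth gradient fields.
#'
#' @param spec a [synth_spec].
#' @param landscape a [les_landuse] (normally the t0 of
#'   [synth_landscape()]); town and settlement sites are tied to its
#'   construction and farmland patches.
#' @return named list of aligned [les_raster]: `POP`, `DR`, `DRS`, `DH`,
#'   `DT`, `SLO`, `ELE`; the target masks are attached as
#'   `attr(, "masks")`.
#' @export
synth_drivers <- function(spec, landscape) {
  stopifnot(inherits(spec, "synth_spec"), inherits(landscape, "les_landuse"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 10007L)
  nr <- spec$rows; nc <- spec$cols; cs <- spec$cell_size
  v <- landscape$values
  # river: lateral random walk top to bottom
  river <- matrix(FALSE, nr, nc)
  col <- sample.int(nc, 1)
  for (i in seq_len(nr)) {
    col <- min(max(col + sample(-1:1, 1), 1), nc)
    river[i, col] <- TRUE
  }
  # highway: straight line across the map
  road <- matrix(FALSE, nr, nc)
  r0 <- sample.int(nr, 1); r1 <- sample.int(nr, 1)
  cols <- seq_len(nc)
  rr <- round(r0 + (r1 - r0) * (cols - 1) / (nc - 1))
  road[cbind(rr, cols)] <- TRUE
  # towns: a handful of construction cells far apart
  built <- which(v == 5)
  towns <- matrix(FALSE, nr, nc)
  towns[if (length(built) >= 5) sample(built, 5) else
        sample.int(nr * nc, 5)] <- TRUE
  # rural settlements: small clusters on farmland
  rural <- matrix(FALSE, nr, nc)
  farm <- which(v == 1)
  site <- if (length(farm) >= 30) sample(farm, 30) else
    sample.int(nr * nc, 30)
  rural[site] <- TRUE
  mk <- function(m) les_raster(m + 0, cell_size = cs)
  DR <- euclidean_distance(mk(river))
  DH <- euclidean_distance(mk(road))
  DT <- euclidean_distance(mk(towns))
  DRS <- euclidean_distance(mk(rural))
  POP <- pmax(spec$pop_scale * exp(-DT$values / 1500) +
                stats::rnorm(nr * nc, 0, spec$pop_noise_sd), 0)
  ELE <- 600 * .smooth_field(matrix(stats::runif(64), 8, 8), nr, nc) +
    outer(seq(300, 0, length.out = nr), seq(0, 80, length.out = nc), "+")
  gy <- rbind(ELE[2, ] - ELE[1, ],
              (ELE[-(1:2), ] - ELE[-((nr - 1):nr), ]) / 2,
              ELE[nr, ] - ELE[nr - 1, ])
  gx <- cbind(ELE[, 2] - ELE[, 1],
              (ELE[, -(1:2)] - ELE[, -((nc - 1):nc)]) / 2,
              ELE[, nc] - ELE[, nc - 1])
  SLO <- atan(sqrt(gx^2 + gy^2) / cs) * 180 / pi
  out <- list(POP = les_raster(POP, cell_size = cs), DR = DR, DRS = DRS,
              DH = DH, DT = DT, SLO = les_raster(SLO, cell_size = cs),
              ELE = les_raster(ELE, cell_size = cs))
  attr(out, "masks") <- list(river = river, road = road, towns = towns,
                             rural = rural)
  out
}

#' Generate a per-unit indicator table
#'
#' Divides the map into `units_dim` x `units_dim` grid units and draws the
#' nineteen shipped indicators. In coupled mode (default, when a landscape
#' is given) the land-cover-share indicators -- proportion of construction
#' (D5), woodland (D7) and water (D8) -- are the actual class shares of
#' each unit plus noise, so the table reflects the landscape it sits on;
#' the remaining indicators are independent draws around
#' indicator-specific levels.
#'
#' @param spec a [synth_spec].
#' @param landscape optional [les_landuse] for coupled mode.
#' @return an [indicator_table]; the unit-id matrix mapping cells to units
#'   is attached as `attr(, "unit_of_cell")`.
#' @export
synth_indicators <- function(spec, landscape = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 20011L)
  nd <- spec$units_dim
  m <- nd * nd
  meta <- psr_indicators()
  base_level <- stats::setNames(stats::runif(nrow(meta), 50, 150),
                                meta$indicator)
  X <- sapply(meta$indicator, function(j)
    stats::rnorm(m, base_level[j], 0.25 * base_level[j]))
  colnames(X) <- meta$indicator
  unit_of_cell <- NULL
  if (!is.null(landscape)) {
    v <- landscape$values
    ui <- pmin(ceiling(row(v) / (nrow(v) / nd)), nd)
    uj <- pmin(ceiling(col(v) / (ncol(v) / nd)), nd)
    unit_of_cell <- (uj - 1L) * nd + ui
    share <- function(code) {
      s <- tapply(as.numeric(v == code), as.vector(unit_of_cell), mean)
      out <- numeric(m); out[as.integer(names(s))] <- 100 * s
      out
    }
    for (d in c(D5 = 5, D7 = 2, D8 = 4)) {
      nm <- names(which(c(D5 = 5, D7 = 2, D8 = 4) == d))[1]
      X[, nm] <- share(d) + stats::rnorm(m, 0, spec$indicator_noise_sd)
    }
    dim(unit_of_cell) <- dim(v)
  }
  tab <- indicator_table(X, stats::setNames(meta$attribute, meta$indicator))
  attr(tab, "unit_of_cell") <- unit_of_cell
  tab
}

#' Rasterize per-unit values back onto the cell grid
#'
#' @param values numeric vector, one value per grid unit.
#' @param unit_of_cell integer matrix mapping each cell to its unit (from
#'   [synth_indicators()]).
#' @param template a [les_raster] supplying cell size and origin.
#' @return a [les_raster] of cell values.
#' @export
units_to_raster <- function(values, unit_of_cell, template) {
  m <- matrix(values[unit_of_cell], nrow(unit_of_cell), ncol(unit_of_cell))
  les_raster(m, cell_size = template$cell_size, origin = template$origin)
}
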