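#' Restriction mask for conversion to a class
#'
#' Cells available for conversion *to* class `class`: everywhere except
#' cells already of that class, permanent basic farmland, water cells and
#' construction cells in the base map; under the ecological-protection
#' scenario the ecological core zone is additionally closed to
#' construction. (Protected categories are furthermore frozen in the CA:
#' they never change class in either direction.)
#'
#' @param class class code being allocated.
#' @param base base-period [les_landuse].
#' @param protected optional logical matrix of protected cells (e.g.
#'   permanent basic farmland).
#' @param scenario `"ND"` (natural development) or `"EP"` (ecological
#'   protection).
#' @param eco_core logical matrix marking the ecological core zone
#'   (required under `"EP"` when `class` is construction).
#' @param water_code,construction_code legend codes of the always-restricted
#'   base classes.
#' @return logical matrix, `TRUE` where conversion to `class` is allowed.
#' @export
restriction_mask <- function(class, base, protected = NULL,
                             scenario = c("ND", "EP"), eco_core = NULL,
                             water_code = 4, construction_code = 5) {
  scenario <- match.arg(scenario)
  v <- base$values
  avail <- !is.na(v)
  avail[v == class] <- FALSE
  avail[v == water_code] <- FALSE
  avail[v == construction_code] <- FALSE
  if (!is.null(protected)) {
    stopifnot(identical(dim(protected), dim(v)))
    avail[protected] <- FALSE
  }
  if (scenario == "EP" && class == construction_code) {
    if (is.null(eco_core))
      stop("EP scenario needs the ecological core mask for construction")
    stopifnot(identical(dim(eco_core), dim(v)))
    avail[eco_core] <- FALSE
  }
  avail
}

#' Fuzzy membership of a constraint factor
#'
#' Linear min-max membership: increasing for positively correlated
#' factors, decreasing for negative ones.
#'
#' @param raster a non-constant [les_raster] (or matrix).
#' @param sign `+1` / `-1` (or `"+"` / `"-"`).
#' @return membership raster in [0, 1].
#' @export
fuzzy_factor <- function(raster, sign) {
  if (is.character(sign)) sign <- if (sign == "+") 1 else -1
  minmax_rescale(raster, if (sign > 0) "increasing" else "decreasing")
}

#' Weighted linear combination of fuzzy factors
#'
#' S = restriction x sum(w_i * f_i), a convex combination of memberships
#' zeroed on restricted cells.
#'
#' @param factors list of `list(raster, weight)` pairs (memberships in
#'   [0, 1], weights >= 0 summing to 1 within 1e-6).
#' @param restriction logical matrix from [restriction_mask()] (or `NULL`
#'   for none).
#' @return suitability matrix in [0, 1].
#' @export
wlc_combine <- function(factors, restriction = NULL) {
  w <- vapply(factors, function(f) f$weight, numeric(1))
  stopifnot(all(w >= 0))
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1 (got ", sum(w), ")")
  mats <- lapply(factors, function(f)
    if (inherits(f$raster, "les_raster")) f$raster$values else f$raster)
  d <- dim(mats[[1]])
  S <- matrix(0, d[1], d[2])
  for (i in seq_along(mats)) {
    stopifnot(identical(dim(mats[[i]]), d))
    S <- S + w[i] * mats[[i]]
  }
  if (!is.null(restriction)) {
    stopifnot(identical(dim(restriction), d))
    S[!restriction] <- 0
  }
  S
}

#' Build per-class suitability atlases
#'
#' For every class with fitted weights: fuzzify each retained driver with
#' its sign, combine by WLC, and zero the restriction mask. Under the EP
#' scenario the security-index raster may take part as a constraint factor
#' (when present in the stack and the weights table).
#'
#' @param weights a [fit_drivers()] result or its `$table` (columns
#'   `class`, `factor`, `weight`, `sign`).
#' @param stack named list of aligned driver rasters.
#' @param base base-period [les_landuse].
#' @param protected optional protected-cell mask.
#' @param scenario `"ND"` or `"EP"`.
#' @param eco_core ecological core mask (EP).
#' @return object of class `suitability_atlas`: list of per-class [0, 1]
#'   matrices keyed by class code, plus provenance.
#' @export
suitability_atlas <- function(weights, stack, base, protected = NULL,
                              scenario = c("ND", "EP"), eco_core = NULL) {
  scenario <- match.arg(scenario)
  tab <- if (inherits(weights, "driver_weights")) weights$table else weights
  stopifnot(all(c("class", "factor", "weight", "sign") %in% names(tab)))
  .assert_aligned2(stack)
  fuzzy <- list()  # memoize memberships per (factor, sign)
  atlas <- list()
  for (k in sort(unique(tab$class))) {
    rows <- tab[tab$class == k, ]
    facs <- lapply(seq_len(nrow(rows)), function(i) {
      key <- paste(rows$factor[i], rows$sign[i])
      if (is.null(fuzzy[[key]]))
        fuzzy[[key]] <<- fuzzy_factor(stack[[rows$factor[i]]], rows$sign[i])
      list(raster = fuzzy[[key]], weight = rows$weight[i])
    })
    restr <- restriction_mask(k, base, protected, scenario, eco_core)
    atlas[[as.character(k)]] <- wlc_combine(facs, restr)
  }
  structure(list(maps = atlas, scenario = scenario,
                 classes = sort(unique(tab$class)),
                 provenance = list(factors = unique(tab$factor),
                                   protected = !is.null(protected))),
            class = "suitability_atlas")
}

#' @export
print.suitability_atlas <- function(x, ...) {
  cat(sprintf("<suitability_atlas> scenario %s, classes: %s\n", x$scenario,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
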