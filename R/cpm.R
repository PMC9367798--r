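#' Indicator table for grid-unit evaluation
#'
#' Holds raw indicator values per evaluation unit together with each
#' indicator's attribute (whether more of it is better or worse for
#' ecological security). Standardized values live in `$H` after
#' [standardize_indicators()].
#'
#' @param x numeric matrix or data frame, units in rows, indicators in
#'   columns (named).
#' @param attribute character vector (`"positive"`/`"negative"`) per
#'   indicator, recycled names matched to columns of `x`.
#' @param unit_ids optional unit identifiers (default row numbers).
#' @return object of class `indicator_table`.
#' @export
indicator_table <- function(x, attribute, unit_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) >= 2, !is.null(colnames(x)))
  if (!is.null(names(attribute))) attribute <- attribute[colnames(x)]
  attribute <- match.arg(attribute, c("positive", "negative"),
                         several.ok = TRUE)
  if (length(attribute) == 1) attribute <- rep(attribute, ncol(x))
  stopifnot(length(attribute) == ncol(x))
  names(attribute) <- colnames(x)
  structure(list(unit_ids = unit_ids %||% seq_len(nrow(x)),
                 x = x, attribute = attribute, H = NULL),
            class = "indicator_table")
}

#' @export
print.indicator_table <- function(x, ...) {
  cat(sprintf("<indicator_table> %d units x %d indicators (%s)\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$H)) "raw" else "standardized"))
  invisible(x)
}

#' Standardize indicators to [0, 1]
#'
#' Positive indicators: H = (x - min)/(max - min); negative indicators:
#' H = (max - x)/(max - min), min/max taken over all units.
#'
#' @param table an [indicator_table].
#' @return the table with `$H` filled in.
#' @export
standardize_indicators <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  lo <- apply(table$x, 2, min)
  hi <- apply(table$x, 2, max)
  if (any(hi == lo))
    stop("constant indicator column(s): ",
         paste(colnames(table$x)[hi == lo], collapse = ", "))
  H <- sweep(sweep(table$x, 2, lo), 2, hi - lo, "/")
  neg <- table$attribute == "negative"
  H[, neg] <- 1 - H[, neg, drop = FALSE]
  table$H <- H
  table
}

#' Entropy weights for indicators
#'
#' Data-driven weighting where an indicator's weight grows with its
#' dispersion across units: p_ij = H_ij / sum_i H_ij,
#' e_j = -(1/ln m) sum_i p_ij ln p_ij (0 ln 0 := 0),
#' w_j = (1 - e_j) / sum_k (1 - e_k). A column that is constant across
#' units carries no information and gets weight 0; all-zero columns are
#' shifted by 1e-4 before proportioning.
#'
#' @param table an [indicator_table], standardized (or with `$H` supplied);
#'   an unstandardized table is standardized first.
#' @return named weights, >= 0, summing to 1.
#' @export
entropy_weights <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  H <- table$H
  if (is.null(H)) H <- standardize_indicators(table)$H
  m <- nrow(H)
  stopifnot(m >= 2)
  e <- vapply(seq_len(ncol(H)), function(j) {
    h <- H[, j]
    if (max(h) == min(h)) return(1)        # zero information
    if (sum(h) == 0) h <- h + 1e-4
    p <- h / sum(h)
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(m)
  }, numeric(1))
  d <- 1 - e
  if (all(d <= 0)) stop("all indicators are constant; no information")
  d[d < 0] <- 0
  w <- d / sum(d)
  names(w) <- colnames(H)
  w
}

# ---- catastrophe-progression hierarchy ------------------------------------

.cpm_models <- c("fold", "cusp", "swallowtail", "butterfly")

#' Catastrophe-progression hierarchy
#'
#' A tree whose leaves are indicator names and whose internal nodes combine
#' their children with a catastrophe model chosen by child count (1 fold,
#' 2 cusp, 3 swallowtail, 4 butterfly). Each internal node may override the
#' aggregation `principle` (`"complementary"` = mean of normalized controls,
#' `"non-complementary"` = their minimum).
#'
#' `x` is either a nested list (`list(name=, children=list(...),
#' principle=)`, leaves given as character strings) or a path to a YAML
#' file with the same structure.
#'
#' @param x nested list or YAML file path.
#' @return object of class `cpm_hierarchy`.
#' @export
cpm_hierarchy <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- yaml::read_yaml(x)
  root <- .cpm_node(x)
  structure(list(root = root, leaves = .cpm_leaves(root), ranked = FALSE),
            class = "cpm_hierarchy")
}

.cpm_node <- function(x) {
  if (is.character(x)) return(list(leaf = TRUE, name = x))
  stopifnot(is.list(x), !is.null(x$children))
  kids <- lapply(x$children, .cpm_node)
  if (length(kids) < 1 || length(kids) > 4)
    stop("node '", x$name %||% "?", "' must have 1-4 children (has ",
         length(kids), "); only fold/cusp/swallowtail/butterfly exist")
  pr <- x$principle %||% "complementary"
  pr <- match.arg(pr, c("complementary", "non-complementary"))
  list(leaf = FALSE, name = x$name %||% "node", children = kids,
       model = .cpm_models[length(kids)], principle = pr)
}

.cpm_leaves <- function(node) {
  if (node$leaf) return(node$name)
  unlist(lapply(node$children, .cpm_leaves))
}

#' @export
print.cpm_hierarchy <- function(x, ...) {
  cat(sprintf("<cpm_hierarchy> %d leaves, %s\n", length(x$leaves),
              if (x$ranked) "ranked" else "unranked"))
  invisible(x)
}

#' Rank hierarchy children by importance
#'
#' Reorders every internal node's children by descending importance, where
#' a leaf's importance is its entropy weight and an internal node's is the
#' sum of its descendant leaf weights. The most important child becomes
#' control variable a (exponent 1/2), the next b (1/3), and so on. Ties
#' keep declaration order.
#'
#' @param hierarchy a [cpm_hierarchy].
#' @param weights named weights covering every leaf.
#' @return the ranked hierarchy.
#' @export
rank_children <- function(hierarchy, weights) {
  stopifnot(inherits(hierarchy, "cpm_hierarchy"))
  miss <- setdiff(hierarchy$leaves, names(weights))
  if (length(miss)) stop("no weight for leaves: ", paste(miss, collapse = ", "))
  rank1 <- function(node) {
    if (node$leaf) { node$importance <- unname(weights[node$name]); return(node) }
    node$children <- lapply(node$children, rank1)
    imp <- vapply(node$children, `[[`, numeric(1), "importance")
    node$children <- node$children[order(-imp, seq_along(imp))]
    node$importance <- sum(imp)
    node
  }
  hierarchy$root <- rank1(hierarchy$root)
  hierarchy$ranked <- TRUE
  hierarchy
}

#' Aggregate standardized indicators through the hierarchy
#'
#' Bottom-up catastrophe-progression aggregation: at each internal node the
#' k-th ranked child value v is normalized as v^(1/(k+1)) (a -> sqrt,
#' b -> cube root, ...) and the node takes the mean (complementary) or the
#' minimum (non-complementary) of the normalized values. The root value is
#' the raw security index L in [0, 1].
#'
#' @param hierarchy a ranked [cpm_hierarchy].
#' @param H numeric matrix of standardized leaf values in [0, 1]
#'   (units x leaves, named columns), a named vector for a single unit, or
#'   a standardized [indicator_table].
#' @return numeric vector of L per unit.
#' @export
cpm_aggregate <- function(hierarchy, H) {
  stopifnot(inherits(hierarchy, "cpm_hierarchy"))
  if (!hierarchy$ranked) stop("hierarchy must be ranked (rank_children)")
  if (inherits(H, "indicator_table")) {
    if (is.null(H$H)) stop("indicator table is not standardized")
    H <- H$H
  }
  if (is.null(dim(H))) H <- matrix(H, nrow = 1, dimnames = list(NULL, names(H)))
  miss <- setdiff(hierarchy$leaves, colnames(H))
  if (length(miss)) stop("missing leaf columns: ", paste(miss, collapse = ", "))
  if (any(H[, hierarchy$leaves] < -1e-12 | H[, hierarchy$leaves] > 1 + 1e-12,
          na.rm = TRUE))
    stop("leaf values outside [0, 1]")
  agg <- function(node) {
    if (node$leaf) return(pmin(pmax(H[, node$name], 0), 1))
    vals <- vapply(seq_along(node$children), function(k) {
      agg(node$children[[k]])^(1 / (k + 1))
    }, numeric(nrow(H)))
    vals <- matrix(vals, nrow = nrow(H))
    if (node$principle == "complementary") rowMeans(vals)
    else apply(vals, 1, min)
  }
  as.numeric(agg(hierarchy$root))
}

#' Reference affiliation levels n_0 .. n_10
#'
#' Propagates the uniform leaf values 0, 0.1, ..., 1.0 through the
#' hierarchy; the resulting strictly increasing sequence anchors the
#' adjusted index (see [adjust_index()]).
#'
#' @param hierarchy a ranked [cpm_hierarchy].
#' @return numeric vector of 11 strictly increasing levels, n_0 = 0,
#'   n_10 = 1.
#' @export
reference_levels <- function(hierarchy) {
  lv <- vapply(0:10, function(i) {
    H <- matrix(i / 10, nrow = 1, ncol = length(hierarchy$leaves),
                dimnames = list(NULL, hierarchy$leaves))
    cpm_aggregate(hierarchy, H)
  }, numeric(1))
  if (any(diff(lv) <= 0)) stop("reference levels are not strictly increasing")
  lv
}

#' Adjust the raw index onto the affiliation scale
#'
#' Raw catastrophe-progression indices crowd near 1; the adjustment
#' re-expresses L relative to the reference levels. The default
#' `"monotone"` variant returns i*0.1 + (L - n_i)/(n_(i+1) - n_i) * 0.1 for
#' L in [n_i, n_(i+1)], a piecewise-linear order-preserving map onto
#' [0, 1]. The `"verbatim"` variant omits the i*0.1 offset, so every decile
#' maps onto [0, 0.1] (order is preserved only within a decile).
#'
#' @param L numeric raw indices in [0, 1].
#' @param levels output of [reference_levels()].
#' @param variant `"monotone"` (default) or `"verbatim"`.
#' @return adjusted indices.
#' @export
adjust_index <- function(L, levels, variant = c("monotone", "verbatim")) {
  variant <- match.arg(variant)
  stopifnot(length(levels) == 11, all(L >= 0 & L <= 1, na.rm = TRUE))
  i <- findInterval(L, levels, rightmost.closed = TRUE) - 1L
  i[i > 9L] <- 9L
  frac <- (L - levels[i + 1L]) / (levels[i + 2L] - levels[i + 1L])
  out <- frac * 0.1
  if (variant == "monotone") out <- out + i * 0.1
  out
}

# ---- high-level evaluation -------------------------------------------------

#' Evaluate the land ecological security index
#'
#' One-call pipeline: standardize the indicator table, derive entropy
#' weights, rank the hierarchy, aggregate to the raw index L, compute
#' reference levels, and adjust. Returns a classed object carrying all
#' intermediates.
#'
#' @param table an [indicator_table].
#' @param hierarchy a [cpm_hierarchy]; defaults to the shipped
#'   pressure-state-response hierarchy ([psr_hierarchy()]).
#' @param weights optional fixed indicator weights; derived by
#'   [entropy_weights()] when `NULL`.
#' @param variant adjustment variant, see [adjust_index()].
#' @return object of class `lesi` with elements `table`, `weights`,
#'   `hierarchy`, `raw`, `levels`, `adjusted`.
#' @export
lesi <- function(table, hierarchy = psr_hierarchy(), weights = NULL,
                 variant = "monotone") {
  table <- standardize_indicators(table)
  if (is.null(weights)) {
    w_all <- entropy_weights(table)
    weights <- w_all[hierarchy$leaves]
  }
  hierarchy <- rank_children(hierarchy, weights)
  raw <- cpm_aggregate(hierarchy, table$H[, hierarchy$leaves, drop = FALSE])
  lv <- reference_levels(hierarchy)
  adj <- adjust_index(raw, lv, variant)
  structure(list(table = table, weights = weights, hierarchy = hierarchy,
                 raw = raw, levels = lv, adjusted = adj, variant = variant),
            class = "lesi")
}

#' @export
print.lesi <- function(x, ...) {
  cat(sprintf("<lesi> %d units; raw index %.3f-%.3f (mean %.3f)\n",
              length(x$raw), min(x$raw), max(x$raw), mean(x$raw)))
  invisible(x)
}

#' @export
summary.lesi <- function(object, ...) {
  out <- list(n = length(object$raw),
              raw = summary(object$raw),
              adjusted = summary(object$adjusted),
              weights = sort(object$weights, decreasing = TRUE))
  class(out) <- "summary.lesi"
  out
}

#' @export
print.summary.lesi <- function(x, ...) {
  cat("Land ecological security evaluation\n")
  cat(sprintf("  units: %d\n", x$n))
  cat("  raw index:\n"); print(x$raw)
  cat("  adjusted index:\n"); print(x$adjusted)
  cat("  top indicator weights:\n")
  print(round(utils::head(x$weights, 5), 3))
  invisible(x)
}

#' Shipped pressure-state-response hierarchy
#'
#' The default three-criteria (pressure, state, response), nine-factor,
#' nineteen-indicator evaluation tree. Indicator attributes and published
#' reference weights are available via [psr_indicators()].
#'
#' @return a [cpm_hierarchy].
#' @export
psr_hierarchy <- function() {
  fac <- function(name, kids) list(name = name, children = as.list(kids))
  cpm_hierarchy(list(
    name = "LES",
    children = list(
      list(name = "pressure", children = list(
        fac("environmental_pollution", c("D1", "D2")),
        fac("population_growth", c("D3", "D4")),
        fac("urban_expansion", c("D5", "D6")))),
      list(name = "state", children = list(
        fac("environmental_quality", c("D7", "D8")),
        fac("economic_condition", c("D9", "D10")),
        fac("resource_reserves", c("D11", "D12", "D13")))),
      list(name = "response", children = list(
        fac("pollution_treatment", c("D14", "D15")),
        fac("economic_input", c("D16", "D17")),
        fac("engineering_governance", c("D18", "D19")))))))
}

#' Reference indicator metadata
#'
#' The shipped indicator set: code, description, criteria block, attribute
#' and the published reference entropy weight, read from the package's
#' extdata CSV.
#'
#' @return data frame with columns `indicator`, `description`, `criteria`,
#'   `factor`, `attribute`, `weight`.
#' @export
psr_indicators <- function() {
  utils::read.csv(system.file("extdata", "psr_indicators.csv",
                              package = "lesim"),
                  stringsAsFactors = FALSE)
}
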