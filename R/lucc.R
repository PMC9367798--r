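#' Fit a land-use change model
#'
#' The central fitting function: from two dated land-use maps it estimates
#' the Markov transition matrix of the period and, when a driver stack is
#' supplied, per-class binary-logistic constraint-factor weights from a
#' stratified cell sample. The returned object drives demand projection
#' ([predict()]) and spatial allocation ([simulate()]).
#'
#' @param from,to aligned [les_landuse] maps for the period start/end.
#' @param stack optional named list of aligned driver rasters.
#' @param fraction sampling fraction for the logistic fits (default 0.05).
#' @param seed integer seed for the cell sampling.
#' @param alpha significance cutoff for retaining factors.
#' @param include optional per-class factor include-list (see
#'   [fit_drivers()]).
#' @return object of class `lucc` with elements `P`
#'   ([transition_matrix()]), `drivers` (or `NULL`), `from`, `to`.
#' @export
lucc <- function(from, to, stack = NULL, fraction = 0.05, seed = 1,
                 alpha = 0.05, include = NULL) {
  .assert_aligned(from, to)
  P <- transition_matrix(from, to)
  drv <- NULL
  if (!is.null(stack)) {
    stopifnot(check_aligned(c(list(from), unname(stack))))
    drv <- fit_drivers(to, stack, fraction = fraction, seed = seed,
                       alpha = alpha, include = include)
  }
  structure(list(P = P, drivers = drv, from = from, to = to,
                 call = match.call()),
            class = "lucc")
}

#' @export
print.lucc <- function(x, ...) {
  cat("Land-use change model\n")
  cat(sprintf("  classes: %s\n", paste(unname(x$P$legend), collapse = ", ")))
  cat("  transition matrix:\n")
  print(round(x$P$P, 3))
  if (!is.null(x$drivers))
    cat(sprintf("  drivers fitted for %d classes (fraction %.2f, seed %d)\n",
                length(x$drivers$per_class), x$drivers$fraction,
                x$drivers$seed))
  invisible(x)
}

#' @export
summary.lucc <- function(object, ...) {
  dem <- project_demand(object$P)
  out <- list(P = object$P$P, base = object$P$base_counts,
              targets = dem$targets, legend = object$P$legend,
              weights = if (!is.null(object$drivers)) object$drivers$table)
  class(out) <- "summary.lucc"
  out
}

#' @export
print.summary.lucc <- function(x, ...) {
  cat("Land-use change model summary\n  transition matrix:\n")
  print(round(x$P, 3))
  df <- data.frame(class = unname(x$legend),
                   base_cells = as.integer(x$base),
                   projected_cells = as.integer(x$targets))
  cat("  projected demand (one step):\n")
  print(df, row.names = FALSE)
  if (!is.null(x$weights)) {
    cat("  constraint-factor weights:\n")
    w <- x$weights; w$weight <- round(w$weight, 3)
    print(w[c("class", "factor", "weight", "sign", "p_value")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.lucc <- function(object, ...) {
  if (is.null(object$drivers)) return(object$P$P)
  object$drivers$table
}

#' Project class demands forward
#'
#' Applies the fitted transition matrix to the end-period class counts
#' (or supplied counts) for `steps` transitions and returns integer cell
#' targets per class.
#'
#' @param object a [lucc] model.
#' @param base_counts starting cells per class (default: end-period map).
#' @param steps number of Markov steps (default 1).
#' @param ... unused.
#' @return named integer vector of target cells per class.
#' @export
predict.lucc <- function(object, base_counts = NULL, steps = 1, ...) {
  if (is.null(base_counts)) {
    codes <- as.integer(names(object$to$legend))
    v <- object$to$values
    base_counts <- stats::setNames(
      as.numeric(table(factor(v[!is.na(v)], levels = codes))), codes)
  }
  cnt <- base_counts
  for (s in seq_len(steps)) cnt <- project_demand(object$P, cnt)$targets
  cnt
}

#' Simulate a future land-use map
#'
#' Runs the cellular automaton: the fitted transition matrix sets the
#' quantity of change from the end-period map and the suitability atlas
#' plus 5x5 contiguity place it. The allocation is deterministic; `seed`
#' is accepted for the [stats::simulate()] contract and recorded in the
#' run log.
#'
#' @param object a [lucc] model.
#' @param nsim number of maps (identical when > 1; the CA is
#'   deterministic).
#' @param seed recorded in the run log.
#' @param atlas a [suitability_atlas] (required).
#' @param base starting map (default: the model's end-period map).
#' @param cycles,window CA configuration (defaults 10 and 5).
#' @param protected optional protected mask folded into the frozen cells.
#' @param ... passed to [ca_simulate()].
#' @return a `ca_result` (or list of them when `nsim > 1`).
#' @export
simulate.lucc <- function(object, nsim = 1, seed = NULL, atlas, base = NULL,
                          cycles = 10, window = 5, protected = NULL, ...) {
  base <- base %||% object$to
  run <- function() ca_simulate(base, object$P, atlas, cycles = cycles,
                                window = window, protected = protected, ...)
  if (nsim == 1) {
    res <- run()
    res$log$seed <- seed
    res
  } else {
    lapply(seq_len(nsim), function(i) { r <- run(); r$log$seed <- seed; r })
  }
}

#' @export
plot.lucc <- function(x, ...) {
  P <- x$P$P
  graphics::image(seq_len(nrow(P)), seq_len(ncol(P)),
                  t(P[nrow(P):1, ]), axes = FALSE,
                  xlab = "to", ylab = "from",
                  main = "Transition probabilities", ...)
  graphics::axis(1, seq_len(ncol(P)), colnames(P))
  graphics::axis(2, seq_len(nrow(P)), rev(rownames(P)))
  invisible(x)
}
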