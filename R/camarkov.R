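#' Markov transition matrix between two land-use maps
#'
#' P[u, v] = (cells of class u at the base date that are v at the later
#' date) / (cells of u at the base date), over non-nodata cells. Classes
#' absent at the base date carry identity rows.
#'
#' @param from,to aligned [les_landuse] maps sharing a legend.
#' @return object of class `transition_matrix`: row-stochastic 6x6 `P`,
#'   base-date cell counts, legend.
#' @export
transition_matrix <- function(from, to) {
  .assert_aligned(from, to)
  if (!identical(from$legend, to$legend)) stop("legend mismatch")
  codes <- as.integer(names(from$legend))
  ok <- !is.na(from$values) & !is.na(to$values)
  cross <- table(factor(from$values[ok], levels = codes),
                 factor(to$values[ok], levels = codes))
  counts <- rowSums(cross)
  P <- matrix(0, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (i in seq_along(codes)) {
    P[i, ] <- if (counts[i] > 0) cross[i, ] / counts[i]
              else as.numeric(seq_along(codes) == i)  # identity row
  }
  structure(list(P = P, base_counts = stats::setNames(as.numeric(counts),
                                                      codes),
                 legend = from$legend),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>\n")
  print(round(x$P, 3))
  invisible(x)
}

#' Project integer class demands
#'
#' Flow matrix F = diag(base) P rounded per row by largest remainder so
#' each row sums exactly to its base count; targets are the column sums.
#' The total cell count is conserved exactly.
#'
#' @param P a [transition_matrix()] (or bare row-stochastic matrix).
#' @param base_counts cells per class at the base date (defaults to the
#'   counts stored in `P`).
#' @return list: `targets` (cells per class), `flow` (integer from-to
#'   matrix), `change` (off-diagonal flow).
#' @export
project_demand <- function(P, base_counts = NULL) {
  if (inherits(P, "transition_matrix")) {
    base_counts <- base_counts %||% P$base_counts
    P <- P$P
  }
  stopifnot(!is.null(base_counts), nrow(P) == length(base_counts),
            all(abs(rowSums(P) - 1) < 1e-9))
  flow <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  for (i in seq_len(nrow(P)))
    flow[i, ] <- lr_round(base_counts[i] * P[i, ], round(base_counts[i]))
  targets <- colSums(flow)
  change <- flow; diag(change) <- 0L
  list(targets = targets, flow = flow, change = change)
}

#' Neighborhood class fraction
#'
#' Fraction of the (edge-truncated) square window around each cell that
#' currently holds the class; computed exactly with an integral image.
#' Nodata cells count in neither numerator nor the class tally.
#'
#' @param state a [les_landuse] (or integer matrix).
#' @param class class code.
#' @param window odd window side (default 5).
#' @return matrix of fractions in [0, 1].
#' @export
neighborhood_factor <- function(state, class, window = 5) {
  stopifnot(window %% 2 == 1, window >= 3)
  v <- if (inherits(state, "les_raster")) state$values else state
  box_count <- function(m) {
    # sum of m over the window at each cell, via 2-D cumulative sums
    nr <- nrow(m); nc <- ncol(m); h <- (window - 1) / 2
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    cs <- t(cs)
    pad <- matrix(0, nr + 1, nc + 1)
    pad[-1, -1] <- cs
    r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
    c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
    pad[r2 + 1, c2 + 1, drop = FALSE] - pad[r1, c2 + 1, drop = FALSE] -
      pad[r2 + 1, c1, drop = FALSE] + pad[r1, c1, drop = FALSE]
  }
  inside <- matrix(1, nrow(v), ncol(v))
  cls <- matrix(as.numeric(!is.na(v) & v == class), nrow(v), ncol(v))
  box_count(cls) / box_count(inside)
}

#' One cellular-automaton allocation cycle
#'
#' Allocates the cycle's share of each from-to demand: the cumulative
#' target after cycle t of T is the largest-remainder rounding of
#' t/T x total change. Candidate cells of the losing class are scored by
#' suitability x (0.01 + neighborhood fraction of the gaining class);
#' gaining classes are processed in descending remaining demand, each cell
#' changes at most once per cycle, frozen and zero-suitability cells never
#' change, and ties fall to (row, col) lexicographic order.
#'
#' @param state integer matrix of current class codes.
#' @param atlas a [suitability_atlas] (per-class [0, 1] matrices).
#' @param demand integer from-to change matrix (rows lose, columns gain).
#' @param allocated integer matrix of conversions already made.
#' @param cycle,cycles current cycle t and total T.
#' @param frozen logical matrix of immutable cells.
#' @param window neighborhood window side.
#' @return list: updated `state`, `allocated`, `shortfall` log (data
#'   frame of unmet pair demands this cycle).
#' @export
allocate_cycle <- function(state, atlas, demand, allocated, cycle, cycles,
                           frozen = NULL, window = 5) {
  codes <- as.integer(rownames(demand))
  nr <- nrow(state)
  if (is.null(frozen)) frozen <- matrix(FALSE, nr, ncol(state))
  # cumulative pair targets after this cycle (flattened largest remainder)
  cum <- matrix(lr_round(as.numeric(demand) * cycle / cycles,
                         round(sum(demand) * cycle / cycles)),
                nrow(demand), dimnames = dimnames(demand))
  todo <- pmax(cum - allocated, 0L)
  locked <- matrix(FALSE, nr, ncol(state))
  shortfall <- NULL
  gain_order <- order(-colSums(todo), seq_len(ncol(todo)))
  for (vi in gain_order) {
    if (colSums(todo)[vi] == 0) next
    vcode <- codes[vi]
    Q <- atlas$maps[[as.character(vcode)]]
    if (is.null(Q)) Q <- matrix(0, nr, ncol(state))
    h <- neighborhood_factor(state, vcode, window)
    score <- Q * (0.01 + h)
    src_order <- order(-todo[, vi], seq_len(nrow(todo)))
    for (ui in src_order) {
      need <- todo[ui, vi]
      if (need == 0 || ui == vi) next
      ucode <- codes[ui]
      cand <- which(!is.na(state) & state == ucode & !frozen & !locked &
                    Q > 0)
      if (length(cand) == 0 && need > 0) {
        shortfall <- rbind(shortfall,
                           data.frame(cycle = cycle, from = ucode,
                                      to = vcode, unmet = need))
        next
      }
      take <- min(need, length(cand))
      # rank by score desc, ties by linear (column-major) index =
      # (col, row); convert to (row, col) lexicographic tie-break
      rr <- (cand - 1L) %% nr + 1L
      cc <- (cand - 1L) %/% nr + 1L
      ord <- order(-score[cand], rr, cc)
      sel <- cand[ord[seq_len(take)]]
      state[sel] <- vcode
      locked[sel] <- TRUE
      allocated[ui, vi] <- allocated[ui, vi] + take
      if (take < need)
        shortfall <- rbind(shortfall,
                           data.frame(cycle = cycle, from = ucode,
                                      to = vcode, unmet = need - take))
    }
  }
  list(state = state, allocated = allocated, shortfall = shortfall)
}

#' CA-Markov land-use simulation
#'
#' Runs `cycles` allocation cycles, distributing the Markov-projected
#' from-to change linearly over cycles and placing it by suitability and
#' 5x5 neighborhood contiguity. Deterministic given identical inputs.
#'
#' @param base base [les_landuse] to project forward.
#' @param P a [transition_matrix()].
#' @param atlas a [suitability_atlas].
#' @param cycles number of CA cycles (default 10).
#' @param window neighborhood window side (odd, default 5).
#' @param frozen logical matrix of immutable cells (default: water,
#'   construction at base, plus any `protected` mask).
#' @param protected optional protected-cell mask folded into `frozen`.
#' @param water_code,construction_code codes frozen by default.
#' @return object of class `ca_result`: `map` (simulated [les_landuse]),
#'   `log` (demand, allocations, shortfalls).
#' @export
ca_simulate <- function(base, P, atlas, cycles = 10, window = 5,
                        frozen = NULL, protected = NULL,
                        water_code = 4, construction_code = 5) {
  stopifnot(inherits(base, "les_landuse"), cycles >= 1)
  v <- base$values
  if (is.null(frozen)) {
    frozen <- !is.na(v) & (v == water_code | v == construction_code)
    if (!is.null(protected)) frozen <- frozen | protected
  }
  dem <- project_demand(P)
  demand <- dem$change
  allocated <- matrix(0L, nrow(demand), ncol(demand),
                      dimnames = dimnames(demand))
  state <- v
  shortfalls <- NULL
  for (t in seq_len(cycles)) {
    step <- allocate_cycle(state, atlas, demand, allocated, t, cycles,
                           frozen, window)
    state <- step$state
    allocated <- step$allocated
    shortfalls <- rbind(shortfalls, step$shortfall)
  }
  out <- base
  out$values <- state
  structure(list(map = out,
                 log = list(demand = demand, allocated = allocated,
                            shortfall = shortfalls, cycles = cycles,
                            window = window, targets = dem$targets)),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> %d cycles, %d x %d window; allocated %d of %d\n",
              x$log$cycles, x$log$window, x$log$window,
              sum(x$log$allocated), sum(x$log$demand)))
  invisible(x)
}
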