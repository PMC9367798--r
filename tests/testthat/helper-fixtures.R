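# shared fixtures and independent oracles, built in code

# small land-use map with all six classes
toy_map <- function(cell_size = 30) {
  m <- matrix(c(1, 1, 2, 2,
                1, 1, 2, 2,
                3, 4, 5, 5,
                6, 4, 5, 5), 4, 4, byrow = TRUE)
  les_landuse(m, cell_size = cell_size)
}

# brute-force all-pairs minimum distance (oracle for the distance transform)
brute_distance <- function(target, cell_size = 1) {
  tg <- which(target, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(target), ncol(target))
  for (i in seq_len(nrow(target))) for (j in seq_len(ncol(target)))
    out[i, j] <- sqrt(min((i - tg[, 1])^2 + (j - tg[, 2])^2)) * cell_size
  out
}

# exhaustive enumeration of ordered k-partitions of sorted values (oracle
# for Fisher-Jenks): returns minimal within-class SSD breakpoints
brute_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_ends <- NULL
  cuts <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(cuts))) {
    ends <- c(cuts[, ci], n)
    starts <- c(1, utils::head(ends, -1) + 1)
    cost <- sum(mapply(function(a, b) ssd(x[a:b]), starts, ends))
    if (cost < best - 1e-12) { best <- cost; best_ends <- ends }
  }
  x[utils::head(best_ends, -1)]
}

# exhaustive greedy selection (oracle for one CA allocation pair):
# top-`demand` scoring eligible cells of class `from`, score Q*(0.01+h),
# ties by (row, col)
brute_allocate <- function(state, Q, from, to, demand, frozen = NULL,
                           window = 5) {
  if (is.null(frozen)) frozen <- matrix(FALSE, nrow(state), ncol(state))
  h <- neighborhood_factor(state, to, window)
  score <- Q * (0.01 + h)
  elig <- which(state == from & !frozen & Q > 0)
  rr <- (elig - 1L) %% nrow(state) + 1L
  cc <- (elig - 1L) %/% nrow(state) + 1L
  sel <- elig[order(-score[elig], rr, cc)][seq_len(min(demand, length(elig)))]
  out <- state
  out[sel] <- to
  out
}

# random valid CPM hierarchy over `nl` leaves (for property tests)
random_hierarchy <- function(nl, seed) {
  set.seed(seed)
  leaves <- paste0("L", seq_len(nl))
  build <- function(items) {
    if (length(items) == 1) return(items[[1]])
    ng <- max(1, min(4, ceiling(length(items) / sample(1:3, 1))))
    grp <- sort(rep_len(seq_len(ng), length(items)))
    kids <- lapply(split(items, grp), build)
    list(name = paste0("n", sample.int(1e6, 1)), children = unname(kids))
  }
  h <- build(as.list(leaves))
  if (is.character(h)) h <- list(name = "root", children = list(h))
  cpm_hierarchy(h)
}

# a small synthetic world shared across tests (cached per session)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synth_spec(rows = 80, cols = 80, seed = 101)
      lw <- synth_landscape(spec)
      drv <- synth_drivers(spec, lw$t0)
      cache <<- list(spec = spec, lw = lw, drv = drv)
    }
    cache
  }
})
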