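#' Largest-remainder integer rounding
#'
#' Rounds a non-negative vector to integers that sum exactly to `total`
#' (default: the rounded sum). Units go to the floors first; the remaining
#' units are handed out by descending fractional remainder, ties broken by
#' position.
#'
#' @param x non-negative numeric vector.
#' @param total integer total the result must sum to.
#' @return integer vector, same length as `x`, summing to `total`.
#' @export
lr_round <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), total >= 0)
  f <- floor(x)
  left <- as.integer(round(total - sum(f)))
  if (left < 0) { # total below the floors: take back from smallest remainders
    ord <- order(x - f, seq_along(x))
    take <- ord[f[ord] > 0][seq_len(min(-left, sum(f > 0)))]
    f[take] <- f[take] - 1
    return(as.integer(f))
  }
  if (left > 0) {
    ord <- order(-(x - f), seq_along(x))
    f[ord[seq_len(left)]] <- f[ord[seq_len(left)]] + 1
  }
  as.integer(f)
}
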