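#' Stratified random sample of presence/absence cells
#'
#' Draws floor(fraction * n1) cells of the class (label 1) and
#' floor(fraction * n0) other non-nodata cells (label 0), uniformly
#' without replacement within each stratum, reproducibly by seed.
#'
#' @param landuse a [les_landuse].
#' @param class class code to sample as presence.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer RNG seed (mandatory, recorded in the result).
#' @return data frame with columns `row`, `col`, `label` and attribute
#'   `seed`.
#' @export
sample_points <- function(landuse, class, fraction, seed) {
  stopifnot(inherits(landuse, "les_landuse"),
            fraction > 0, fraction <= 1, !missing(seed))
  v <- landuse$values
  ones <- which(!is.na(v) & v == class)
  zeros <- which(!is.na(v) & v != class)
  if (!length(ones)) stop("class ", class, " absent from map")
  n1 <- floor(fraction * length(ones))
  n0 <- floor(fraction * length(zeros))
  if (n1 == 0 || n0 == 0) stop("fraction yields an empty stratum")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick1 <- sort(sample(ones, n1))
  pick0 <- sort(sample(zeros, n0))
  idx <- c(pick1, pick0)
  out <- data.frame(row = (idx - 1L) %% nrow(v) + 1L,
                    col = (idx - 1L) %/% nrow(v) + 1L,
                    label = rep(c(1L, 0L), c(n1, n0)))
  attr(out, "seed") <- seed
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Extract driver values at sampled cells
#'
#' @param stack named list of aligned [les_raster] drivers.
#' @param sample output of [sample_points()].
#' @return data frame: `label` plus one column per driver.
#' @export
extract_drivers <- function(stack, sample) {
  stopifnot(is.list(stack), length(stack) >= 1, !is.null(names(stack)))
  .assert_aligned2(stack)
  idx <- cbind(sample$row, sample$col)
  out <- data.frame(label = sample$label)
  for (nm in names(stack)) out[[nm]] <- stack[[nm]]$values[idx]
  out
}

.assert_aligned2 <- function(stack) {
  if (!check_aligned(unname(stack))) stop("driver stack is not aligned")
  if (anyDuplicated(names(stack))) stop("duplicate driver names")
}

#' Collinearity screen: VIF and tolerance
#'
#' VIF_j = 1/(1 - R2_j) from regressing factor j on all other factors;
#' TOL_j = 1/VIF_j. Factors with VIF >= 10 (or a singular fit) are
#' flagged.
#'
#' @param data data frame of factor columns (a `label` column, if present,
#'   is ignored).
#' @return data frame with columns `factor`, `vif`, `tol`, `flag`.
#' @export
collinearity <- function(data) {
  X <- data[setdiff(names(data), "label")]
  stopifnot(ncol(X) >= 2, nrow(X) > ncol(X) + 1)
  out <- data.frame(factor = names(X), vif = NA_real_, tol = NA_real_,
                    flag = FALSE)
  for (j in seq_along(X)) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    # a singular fit warns about a perfect summary; the flag reports it
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) {
      out$vif[j] <- Inf; out$tol[j] <- 0; out$flag[j] <- TRUE
    } else {
      out$vif[j] <- 1 / (1 - r2)
      out$tol[j] <- 1 - r2
      out$flag[j] <- out$vif[j] >= 10
    }
  }
  out
}

#' Binary logistic regression on standardized drivers
#'
#' Maximum-likelihood logit fit of the presence label on z-scored factors
#' (so coefficient magnitudes are comparable across units of measure),
#' with two-sided Wald p-values. Perfect separation or non-convergence
#' triggers a ridge-penalized (1e-6) iteratively reweighted least squares
#' refit, flagged in the result.
#'
#' @param data data frame with a 0/1 `label` column and factor columns.
#' @param factors factor names to use (default: all non-label columns).
#' @return object of class `blr_fit`: `coef`, `se`, `z`, `p` (slopes
#'   only), `intercept`, `separation`, `converged`, `scale` (means/sds).
#' @export
fit_blr <- function(data, factors = setdiff(names(data), "label")) {
  stopifnot(all(c(0, 1) %in% data$label))
  X <- as.matrix(data[factors])
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  if (any(sd == 0)) stop("constant factor: ",
                         paste(factors[sd == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  y <- data$label
  df <- data.frame(y = y, Z)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # separation can also complete "successfully" with divergent coefficients
  # and fitted probabilities at the 0/1 boundary
  if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    sep <- TRUE
  if (sep || !fit$converged) {
    co <- .ridge_logit(cbind(1, Z), y, lambda = 1e-6)
    b <- co$beta; se <- co$se
    sep <- TRUE
    conv <- co$converged
  } else {
    sm <- summary(fit)$coefficients
    b <- sm[, 1]; se <- sm[, 2]
    conv <- TRUE
  }
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(coef = stats::setNames(b[-1], factors),
                 se = stats::setNames(se[-1], factors),
                 z = stats::setNames(z[-1], factors),
                 p = stats::setNames(p[-1], factors),
                 intercept = unname(b[1]), separation = sep,
                 converged = conv, scale = list(mean = mu, sd = sd)),
            class = "blr_fit")
}

# Newton/IRLS logistic with ridge penalty on all coefficients
.ridge_logit <- function(X, y, lambda = 1e-6, maxit = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    g <- crossprod(X, y - p) - lambda * b
    H <- crossprod(X * W, X) + lambda * diag(ncol(X))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) { conv <- TRUE; break }
  }
  eta <- drop(X %*% b); p <- 1 / (1 + exp(-eta))
  H <- crossprod(X * (p * (1 - p)), X) + lambda * diag(ncol(X))
  se <- sqrt(diag(solve(H)))
  list(beta = b, se = se, converged = conv)
}

#' @export
print.blr_fit <- function(x, ...) {
  cat(sprintf("<blr_fit> %d factors%s\n", length(x$coef),
              if (x$separation) " (separation: ridge fallback)" else ""))
  print(round(cbind(coef = x$coef, p = x$p), 4))
  invisible(x)
}

#' Signed constraint-factor weights from a logistic fit
#'
#' Drops factors whose Wald p-value is at or above `alpha`, then
#' normalizes the absolute standardized coefficients of the remainder to
#' unit sum; the coefficient sign is carried separately and later orients
#' the fuzzy membership of the factor.
#'
#' @param fit a [fit_blr()] result (or a named coefficient vector plus
#'   `p`).
#' @param alpha significance cutoff (default 0.05).
#' @param p p-values when `fit` is a bare coefficient vector.
#' @return data frame `factor`, `coefficient`, `p_value`, `weight`,
#'   `sign` (+1/-1); weights sum to 1.
#' @export
derive_weights <- function(fit, alpha = 0.05, p = NULL) {
  if (inherits(fit, "blr_fit")) { co <- fit$coef; p <- fit$p }
  else co <- fit
  stopifnot(length(co) == length(p))
  keep <- p < alpha & co != 0
  if (!any(keep)) stop("no significant factors at alpha = ", alpha)
  w <- abs(co[keep]) / sum(abs(co[keep]))
  data.frame(factor = names(co)[keep],
             coefficient = unname(co[keep]),
             p_value = unname(p[keep]),
             weight = unname(w),
             sign = ifelse(co[keep] > 0, 1L, -1L),
             row.names = NULL)
}

#' Fit driver weights for every land class
#'
#' For each class present in the end-period map, samples presence/absence
#' cells, screens collinearity, fits the logistic regression and derives
#' signed weights. The per-class weight tables mirror the structure of a
#' constraint-factor table: one unit-sum row of signed weights per class.
#'
#' @param landuse_to end-period [les_landuse] (presence is membership at
#'   period end).
#' @param stack named list of aligned driver rasters.
#' @param fraction sampling fraction (default 0.05).
#' @param seed integer seed; class k uses `seed + k`.
#' @param alpha significance cutoff for retaining factors.
#' @param include optional named list: class code -> character vector of
#'   factors to consider (a priori inclusion list).
#' @param classes class codes to fit (default: all present).
#' @return object of class `driver_weights`: per-class list with `fit`,
#'   `vif`, `weights`; plus a combined `table`.
#' @export
fit_drivers <- function(landuse_to, stack, fraction = 0.05, seed = 1,
                        alpha = 0.05, include = NULL, classes = NULL) {
  v <- landuse_to$values
  present <- sort(unique(v[!is.na(v)]))
  classes <- classes %||% present
  res <- list()
  rows <- list()
  for (k in classes) {
    facs <- include[[as.character(k)]] %||% names(stack)
    smp <- sample_points(landuse_to, k, fraction, seed + k)
    dat <- extract_drivers(stack[facs], smp)
    vif <- collinearity(dat)
    fit <- fit_blr(dat, facs)
    w <- tryCatch(derive_weights(fit, alpha), error = function(e) NULL)
    if (is.null(w)) {   # e.g. a rare class with an uninformative sample
      warning("class ", k, ": no significant factors at alpha = ", alpha,
              "; class skipped", call. = FALSE)
      next
    }
    res[[as.character(k)]] <- list(fit = fit, vif = vif, weights = w)
    rows[[as.character(k)]] <-
      cbind(class = k, merge(w, vif, by = "factor", sort = FALSE))
  }
  structure(list(per_class = res, table = do.call(rbind, rows),
                 fraction = fraction, seed = seed, alpha = alpha),
            class = "driver_weights")
}

#' @export
print.driver_weights <- function(x, ...) {
  cat(sprintf("<driver_weights> %d classes, fraction %.2f, seed %d\n",
              length(x$per_class), x$fraction, x$seed))
  df <- x$table
  df$weight <- round(df$weight, 3)
  df$vif <- round(df$vif, 2)
  print(df[c("class", "factor", "weight", "sign", "vif")],
        row.names = FALSE)
  invisible(x)
}
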