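## Nonmetric multidimensional scaling of the monthly descriptor panel.
##
## The optimizer is implemented here in full - isotonic regression of
## configuration distances on the rank order of the input dissimilarities
## (pool-adjacent-violators), with Guttman-transform (majorization) updates
## of the configuration and multiple random restarts - because the stress
## function and its tie treatment are the substance of this stage. External
## NMDS implementations are used only as cross-checks in the test suite.

#' Prepare a descriptor matrix for ordination
#'
#' Drops all-zero descriptor columns (e.g. the cannibal fraction in a year
#' without cannibalistic links), which carry no information and would make
#' the Wisconsin column standardization undefined; a message names any
#' dropped column.
#'
#' @param dm descriptor matrix or data.frame (rows = months).
#' @return Numeric matrix with informative columns only.
#' @export
prepare_descriptors <- function(dm) {
  m <- as.matrix(dm)
  zero <- colSums(m != 0) == 0
  if (any(zero))
    message("dropping all-zero descriptor column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
  m[, !zero, drop = FALSE]
}

#' Wisconsin double standardization
#'
#' Divides each column by its maximum, then each row by its sum. Applied to
#' the descriptor matrix before Bray-Curtis distances to stop descriptors
#' with large numeric ranges (e.g. link counts) from swamping proportions.
#'
#' @param x non-negative numeric matrix (rows = months, columns =
#'   descriptors); no all-zero column.
#' @return Matrix of the same shape; every row sums to 1.
#' @export
wisconsin <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("wisconsin standardization needs non-negative entries")
  cmax <- apply(x, 2, max)
  if (any(cmax == 0))
    stop("all-zero column(s): ",
         paste(colnames(x)[cmax == 0], collapse = ", "))
  x <- sweep(x, 2, cmax, "/")
  rsum <- rowSums(x)
  if (any(rsum == 0))
    stop("all-zero row(s) after column standardization: ",
         paste(rownames(x)[rsum == 0], collapse = ", "))
  sweep(x, 1, rsum, "/")
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over columns; entries lie in
#' \[0, 1\]. A pair of all-zero rows has no defined dissimilarity and is
#' returned as `NA` with a warning.
#'
#' @param x non-negative numeric matrix (rows = objects).
#' @return Symmetric matrix with zero diagonal and the row names of `x`.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis needs non-negative entries")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- sum(x[i, ] + x[j, ])
    d[i, j] <- d[j, i] <- if (denom == 0) NA_real_ else
      sum(abs(x[i, ] - x[j, ])) / denom
  }
  if (anyNA(d)) warning("undefined Bray-Curtis pair(s): two all-zero rows")
  d
}

#' Weighted pool-adjacent-violators (isotonic regression)
#'
#' Least-squares non-decreasing fit to `y` with weights `w`.
#'
#' @param y numeric vector.
#' @param w positive weights (default 1).
#' @return Non-decreasing fitted values, same length as `y`.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric())
  ## blocks as stacks of (value, weight, size)
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = sz[seq_len(top)])
}

## Monotone disparities for configuration distances `delta` given input
## dissimilarities `d`. Primary tie treatment: within a block of tied d the
## deltas are pre-sorted, so tied input distances may take unordered
## disparities. Secondary: tied d values are forced to share one disparity.
.disparities <- function(d, delta, ties = "primary") {
  if (ties == "primary") {
    o <- order(d, delta)
    dhat <- numeric(length(d))
    dhat[o] <- pava(delta[o])
  } else {
    o <- order(d)
    blocks <- match(d, sort(unique(d)))
    bmean <- tapply(delta, blocks, mean)
    bw <- tapply(rep(1, length(d)), blocks, sum)
    fit <- pava(as.numeric(bmean), as.numeric(bw))
    dhat <- fit[blocks]
  }
  dhat
}

.lower <- function(m) m[lower.tri(m)]

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a k-dimensional configuration minimizing Kruskal's stress-1,
#' sqrt(sum((dhat - delta)^2) / sum(delta^2)), where delta are configuration
#' distances and dhat are disparities obtained by isotonic regression of
#' delta on the rank order of the input dissimilarities. Each restart
#' alternates the isotonic fit with a Guttman-transform update and stops
#' when stress no longer decreases by `tol`; the first start is metric
#' (classical scaling), the rest are random. The best-stress solution is
#' returned centred and rotated to its principal axes, with a deterministic
#' sign convention.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param k target dimensionality (default 2).
#' @param n_restarts number of random restarts in addition to the metric
#'   start.
#' @param seed integer seed.
#' @param ties `"primary"` (tied input distances free, default) or
#'   `"secondary"` (tied input distances share a disparity).
#' @param maxit,tol iteration cap and stress-decrease tolerance per restart.
#' @return Object of class `lakeweb_nmds`: list with `scores` (n x k),
#'   `stress`, `nonmetric_R2` (= 1 - stress^2), `linear_R2` (squared
#'   Pearson correlation of disparities and configuration distances),
#'   `n_restarts`, `converged`, and the final `delta` and `dhat` vectors
#'   (lower triangle order) for Shepard plots.
#' @export
nmds <- function(d, k = 2, n_restarts = 100, seed = 1,
                 ties = c("primary", "secondary"), maxit = 500, tol = 1e-9) {
  ties <- match.arg(ties)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("NMDS needs at least 4 points")
  if (anyNA(d)) stop("dissimilarity matrix contains NA")
  dv <- .lower(d)
  labs <- rownames(d)

  run_restart <- function(X) {
    best_X <- X
    best_stress <- Inf
    best_sh <- NULL
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(maxit)) {
      delta <- .lower(as.matrix(stats::dist(X)))
      dhat <- .disparities(dv, delta, ties)
      denom <- sum(delta^2)
      stress <- if (denom > 0) sqrt(sum((dhat - delta)^2) / denom) else 0
      if (stress < best_stress) {
        best_stress <- stress
        best_X <- X
        best_sh <- list(delta = delta, dhat = dhat)
      }
      if (prev - stress < tol) {
        converged <- prev - stress >= 0 || stress < tol
        break
      }
      prev <- stress
      ## Guttman transform with the disparities as target distances
      Dm <- matrix(0, n, n)
      Dm[lower.tri(Dm)] <- delta
      Dm <- Dm + t(Dm)
      Hm <- matrix(0, n, n)
      Hm[lower.tri(Hm)] <- dhat
      Hm <- Hm + t(Hm)
      B <- ifelse(Dm > 0, -Hm / Dm, 0)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    list(X = best_X, stress = best_stress, shepard = best_sh,
         converged = converged)
  }

  with_seed(seed, {
    ## metric start: classical scaling, padded if rank-deficient
    X0 <- suppressWarnings(stats::cmdscale(d, k = k))
    if (ncol(X0) < k)
      X0 <- cbind(X0, matrix(0, n, k - ncol(X0)))
    starts <- c(list(X0), lapply(seq_len(n_restarts), function(i)
      matrix(stats::runif(n * k, -1, 1) * max(max(dv), 1), n, k)))
    best <- NULL
    for (X in starts) {
      res <- run_restart(X)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    X <- scale(best$X, scale = FALSE)      # centre at the origin
    sv <- svd(X)
    X <- sv$u %*% diag(sv$d, k)            # principal-axis rotation
    for (j in seq_len(k)) {                # deterministic sign convention
      i <- which.max(abs(X[, j]))
      if (X[i, j] < 0) X[, j] <- -X[, j]
    }
    rownames(X) <- labs
    colnames(X) <- paste0("NMDS", seq_len(k))
    if (best$stress < 1e-3 && max(dv) > 0 && stats::sd(dv) / max(dv) > 1e-6)
      warning("stress is (nearly) zero: the configuration may be a ",
              "degenerate solution (insufficient contrast in the data)")
    sh <- best$shepard
    lin <- if (stats::sd(sh$dhat) > 0 && stats::sd(sh$delta) > 0)
      stats::cor(sh$dhat, sh$delta)^2 else 1
    structure(list(scores = X, stress = best$stress,
                   nonmetric_R2 = 1 - best$stress^2, linear_R2 = lin,
                   n_restarts = n_restarts, converged = best$converged,
                   delta = sh$delta, dhat = sh$dhat, diss = dv),
              class = "lakeweb_nmds")
  })
}

#' @export
print.lakeweb_nmds <- function(x, ...) {
  cat(sprintf(
    "NMDS (%d points, k = %d): stress = %.4g, linear R2 = %.3f, nonmetric R2 = %.3f\n",
    nrow(x$scores), ncol(x$scores), x$stress, x$linear_R2, x$nonmetric_R2))
  invisible(x)
}

#' Fit an external variable onto an ordination
#'
#' Least-squares fit of a (centred) variable on the ordination scores: the
#' returned direction is the unit vector of regression coefficients, `r2`
#' the squared multiple correlation, and `p_perm` a permutation p-value
#' computed by permuting the variable across points,
#' p = (1 + #\{permuted r2 >= observed\}) / (n_perm + 1).
#'
#' @param ord a [nmds()] result (or any list with a `scores` matrix).
#' @param variable numeric vector, one value per ordination point, with at
#'   least two distinct values.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param name label for the variable.
#' @return data.frame row: `variable`, `dir1`, `dir2`, `r2`, `p_perm`.
#' @export
envfit_vector <- function(ord, variable, n_perm = 1000, seed = 1,
                          name = "variable") {
  X <- scale(ord$scores, scale = FALSE)
  n <- nrow(X)
  v <- as.numeric(variable)
  if (length(v) != n) stop("variable length must match the ordination")
  if (anyNA(v)) stop("variable contains NA")
  if (length(unique(v)) < 2) stop("variable is constant")
  Q <- qr.Q(qr(X))
  r2_of <- function(u) {
    uc <- u - mean(u)
    sum(crossprod(Q, uc)^2) / sum(uc^2)
  }
  r2 <- r2_of(v)
  vc <- v - mean(v)
  b <- qr.coef(qr(X), vc)
  dir <- b / sqrt(sum(b^2))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) r2_of(v[sample.int(n)]) >= r2, logical(1)))
  })
  data.frame(variable = name, dir1 = unname(dir[1]), dir2 = unname(dir[2]),
             r2 = r2, p_perm = (1 + exceed) / (n_perm + 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a set of variables onto an ordination
#'
#' @param ord a [nmds()] result.
#' @param vars numeric matrix or data.frame, one column per variable, rows
#'   aligned with the ordination points.
#' @param n_perm,seed as in [envfit_vector()].
#' @return data.frame, one row per variable.
#' @export
envfit_table <- function(ord, vars, n_perm = 1000, seed = 1) {
  vars <- as.matrix(vars)
  out <- lapply(seq_len(ncol(vars)), function(j)
    envfit_vector(ord, vars[, j], n_perm = n_perm, seed = seed + j,
                  name = colnames(vars)[j] %||% paste0("V", j)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
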