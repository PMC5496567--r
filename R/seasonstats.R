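## Seasonal contrasts between the data-driven summer and winter month
## clusters, and interannual composition-similarity checks.

## tie-corrected Kruskal-Wallis H for a response and group factor
.kw_H <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  H <- (12 / (N * (N + 1))) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H / C else 0
}

## all assignments of indices 1..N into groups of the given sizes
.group_assignments <- function(sizes) {
  recurse <- function(remaining, sizes) {
    if (length(sizes) == 1) return(list(list(remaining)))
    first <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- recurse(setdiff(remaining, f), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  recurse(seq_len(sum(sizes)), sizes)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom (as in [stats::kruskal.test()], which supplies the
#' statistic). With `exact = TRUE` the p-value is instead computed from the
#' full permutation distribution of H over all assignments of the pooled
#' observations to groups of the observed sizes - appropriate for the very
#' small group sizes of seasonal month contrasts.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @param exact compute the exact permutation p-value (total n <= 12)?
#' @return Object of class `kw_test`: list with `H`, `df`, `p_value`,
#'   `group_sizes`, `method`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must have at least one observation")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least three observations in total")
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  p <- unname(kt$p.value)
  method <- "chi-square approximation"
  if (exact) {
    if (length(x) > 12)
      stop("exact permutation p-value limited to n <= 12")
    assigns <- .group_assignments(sizes)
    perm_H <- vapply(assigns, function(a) {
      gg <- integer(length(x))
      for (k in seq_along(a)) gg[a[[k]]] <- k
      .kw_H(x, factor(gg))
    }, numeric(1))
    p <- mean(perm_H >= H - 1e-12)
    method <- "exact permutation"
  }
  structure(list(H = H, df = length(groups) - 1L, p_value = p,
                 group_sizes = as.integer(sizes), method = method),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (%s)\n",
              x$H, x$df, x$p_value, x$method))
  invisible(x)
}

#' Summer/winter contrasts for every descriptor
#'
#' For each descriptor: seasonal means, the summer/winter ratio, the
#' percent increase from winter to summer ((summer - winter) / winter), and
#' the Kruskal-Wallis p-value comparing the summer and winter months. Two
#' percent-change conventions coexist deliberately: seasonal mean changes
#' are relative to the winter mean, while month-extreme changes
#' ((max - min) / max, reported in the `extremes` table for S and L) are
#' relative to the maximum month. No multiple-testing correction is applied
#' across descriptors, but a Holm-adjusted column is emitted alongside for
#' transparency.
#'
#' @param dm descriptor matrix ([descriptor_matrix()]), rows = months.
#' @param partition a `season_partition` (or named season vector) aligned
#'   with the rows of `dm`.
#' @param exact use exact permutation Kruskal-Wallis p-values?
#' @return List with `contrasts` (one row per descriptor: means, ratio,
#'   `increase_pct`, `H`, `p`, `p_holm`) and `extremes` (rows S and L:
#'   max, min, `decrease_pct`).
#' @export
seasonal_contrasts <- function(dm, partition, exact = FALSE) {
  season <- if (inherits(partition, "season_partition")) partition$season
            else partition
  if (length(season) != nrow(dm))
    stop("partition must label every row of the descriptor matrix")
  if (!all(c("summer", "winter") %in% season))
    stop("both seasons must be non-empty")
  s_rows <- season == "summer"
  out <- do.call(rbind, lapply(names(dm), function(v) {
    sv <- dm[[v]][s_rows]; wv <- dm[[v]][!s_rows]
    kw <- kruskal_wallis(list(sv, wv), exact = exact)
    data.frame(descriptor = v, summer_mean = mean(sv), winter_mean = mean(wv),
               ratio = mean(sv) / mean(wv),
               increase_pct = 100 * (mean(sv) - mean(wv)) / mean(wv),
               H = kw$H, p = kw$p_value, stringsAsFactors = FALSE)
  }))
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  ext <- do.call(rbind, lapply(intersect(c("S", "L"), names(dm)), function(v) {
    mx <- max(dm[[v]]); mn <- min(dm[[v]])
    data.frame(descriptor = v, max = mx, min = mn,
               decrease_pct = 100 * (mx - mn) / mx, stringsAsFactors = FALSE)
  }))
  list(contrasts = out, extremes = ext)
}

#' Interannual composition similarity for one group
#'
#' Pools the species set recorded per year for the given group and computes
#' pairwise Sorensen similarity (2 |A intersect B| / (|A| + |B|)) between
#' years - the year-on-year stability check behind collapsing the record
#' into a single idealized year.
#'
#' @param samples sample-record table.
#' @param group one of [lakeweb_groups()].
#' @return Symmetric year x year similarity matrix.
#' @export
interannual_similarity <- function(samples, group) {
  sub <- samples[samples$group == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for group ", group)
  years <- sort(unique(sub$year))
  if (length(years) < 2)
    stop("need at least two sampled years for group ", group)
  sets <- lapply(years, function(y) unique(sub$taxon_id[sub$year == y]))
  n <- length(years)
  m <- matrix(1, n, n, dimnames = list(years, years))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- sorensen_similarity(sets[[i]], sets[[j]])
  m
}
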