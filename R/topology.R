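## Link-pattern similarity between monthly webs, data-driven two-season
## extraction, and the partition of links into year-round / summer-only /
## winter-only sets.

#' Sorensen similarity of two link sets
#'
#' 2 |A intersect B| / (|A| + |B|), i.e. 1 minus the Sorensen dissimilarity.
#' Two empty sets are identical in their emptiness and return 1 with a
#' warning.
#'
#' @param a,b character vectors of directed link keys (see [link_set()]) or
#'   any set-like vectors.
#' @return Similarity in \[0, 1\].
#' @export
sorensen_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    warning("both link sets empty: similarity defined as 1")
    return(1)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Month-by-month link-pattern similarity matrix
#'
#' Pairwise Sorensen similarity between the link sets of the 12 monthly
#' webs.
#'
#' @param webs list of 12 [monthly_web()] objects.
#' @return 12 x 12 symmetric matrix with unit diagonal, labelled by month.
#' @export
similarity_matrix <- function(webs) {
  sets <- lapply(webs, link_set)
  n <- length(sets)
  m <- matrix(1, n, n,
              dimnames = list(month.abb[vapply(webs, `[[`, 1L, "month")],
                              month.abb[vapply(webs, `[[`, 1L, "month")]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- sorensen_similarity(sets[[i]], sets[[j]])
  m
}

#' Extract a two-season partition of the months
#'
#' Average-linkage hierarchical clustering (configurable) of the months on
#' 1 - similarity, cut at two clusters. Season labels are assigned by web
#' size, not by calendar: the cluster containing the month with the most
#' links is called summer. The same procedure applied to NMDS scores
#' (Euclidean distances) gives the ordination-based partition; see
#' [season_agreement()] for comparing the two.
#'
#' @param sim 12 x 12 similarity matrix ([similarity_matrix()]), or a
#'   distance matrix if `is_distance = TRUE` (e.g. Euclidean distances
#'   between NMDS scores).
#' @param sizes per-month link counts used to label the summer cluster
#'   (e.g. the `L` column of [web_sizes()]).
#' @param method hierarchical clustering linkage (default `"average"`).
#' @param is_distance is `sim` already a dissimilarity?
#' @return Object of class `season_partition`: list with `season` (named
#'   character vector, `"summer"`/`"winter"` per month) and `tree` (the
#'   `hclust` object).
#' @export
extract_seasons <- function(sim, sizes, method = "average",
                            is_distance = FALSE) {
  sim <- as.matrix(sim)
  d <- if (is_distance) sim else 1 - sim
  if (stats::sd(d[upper.tri(d)]) == 0)
    stop("degenerate similarity: all off-diagonal values equal")
  tree <- stats::hclust(stats::as.dist(d), method = method)
  cl <- stats::cutree(tree, k = 2)
  if (length(sizes) != length(cl))
    stop("sizes must give one link count per month")
  summer_cluster <- cl[which.max(sizes)]
  season <- ifelse(cl == summer_cluster, "summer", "winter")
  names(season) <- rownames(d) %||% month.abb[seq_along(cl)]
  structure(list(season = season, tree = tree), class = "season_partition")
}

#' @export
print.season_partition <- function(x, ...) {
  cat("Two-season partition (by web structure, not calendar):\n")
  cat("  summer:", paste(names(x$season)[x$season == "summer"],
                         collapse = " "), "\n")
  cat("  winter:", paste(names(x$season)[x$season == "winter"],
                         collapse = " "), "\n")
  invisible(x)
}

#' Agreement between two season partitions
#'
#' Fraction of months assigned to the same season by two partitions (label
#' permutations are resolved by taking the better of the two matchings).
#'
#' @param a,b `season_partition` objects or named season vectors.
#' @return Fraction in \[0, 1\].
#' @export
season_agreement <- function(a, b) {
  sa <- if (inherits(a, "season_partition")) a$season else a
  sb <- if (inherits(b, "season_partition")) b$season else b
  stopifnot(length(sa) == length(sb))
  max(mean(sa == sb), mean(sa != sb))
}

#' Partition realized links into year-round, summer-only and winter-only
#'
#' A link is year-round if it is realized in at least one summer and at
#' least one winter month; otherwise it belongs to the season in which it
#' occurs. The three sets are disjoint and together exhaust all links
#' realized in at least one monthly web.
#'
#' @param webs list of 12 [monthly_web()] objects.
#' @param partition a `season_partition` from [extract_seasons()].
#' @return List with character-vector link keys `both_seasons`,
#'   `summer_only`, `winter_only`.
#' @export
partition_links <- function(webs, partition) {
  season <- if (inherits(partition, "season_partition")) partition$season
            else partition
  if (length(season) != length(webs))
    stop("partition must cover all months")
  sets <- lapply(webs, link_set)
  summer_links <- unique(unlist(sets[season == "summer"]))
  winter_links <- unique(unlist(sets[season == "winter"]))
  list(both_seasons = intersect(summer_links, winter_links),
       summer_only = setdiff(summer_links, winter_links),
       winter_only = setdiff(winter_links, summer_links))
}
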