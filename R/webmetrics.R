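## Qualitative network descriptors for binary monthly webs.
##
## Conventions (links stored resource -> consumer):
##   resources(i) = nodes i feeds on;  consumers(i) = nodes feeding on i.
##   A node's "in-degree" in the diet sense is its number of resources.
## Cannibalistic self-links count in L and frac_cannibal but are excluded
## from trophic-level solving and from the top/basal classification.

#' Connectance of a binary web
#'
#' Realised fraction of possible directed links, L / S^2.
#'
#' @param S number of nodes (>= 1).
#' @param L number of links.
#' @return L / S^2.
#' @export
connectance <- function(S, L) {
  if (any(S < 1)) stop("connectance undefined for S < 1")
  L / S^2
}

#' Link density of a binary web
#'
#' Mean number of links per node, L / S.
#'
#' @inheritParams connectance
#' @return L / S.
#' @export
link_density <- function(S, L) {
  if (any(S < 1)) stop("link density undefined for S < 1")
  L / S
}

## adjacency in list form: for each node its resources and consumers
.web_neighbours <- function(web, drop_self = FALSE) {
  lk <- web$links
  if (drop_self && nrow(lk))
    lk <- lk[lk$resource != lk$consumer, , drop = FALSE]
  list(
    resources = lapply(stats::setNames(web$nodes, web$nodes), function(n)
      unique(lk$resource[lk$consumer == n])),
    consumers = lapply(stats::setNames(web$nodes, web$nodes), function(n)
      unique(lk$consumer[lk$resource == n])))
}

#' Prey-averaged trophic levels
#'
#' TL = 1 for basal nodes (no resources); otherwise 1 plus the mean trophic
#' level of the node's resources. Self-links are removed before solving.
#' The defining equations are solved as a linear system; if the system is
#' singular (pure consumer cycles), a damped fixed-point iteration to
#' tolerance 1e-10 is used. A consumer from which no basal node can be
#' reached along diet links has no defined trophic level and gets `NA` with
#' a warning.
#'
#' @param web a [monthly_web()].
#' @return Named numeric vector of trophic levels (>= 1, or `NA` where
#'   undefined).
#' @export
trophic_levels <- function(web) {
  stopifnot(inherits(web, "monthly_web"))
  nodes <- web$nodes
  n <- length(nodes)
  lk <- web$links
  if (nrow(lk)) lk <- lk[lk$resource != lk$consumer, , drop = FALSE]
  ri <- match(lk$resource, nodes)
  ci <- match(lk$consumer, nodes)
  nres <- tabulate(ci, nbins = n)          # number of resources per node
  basal <- nres == 0

  ## reachability down to a basal node along consumer -> resource edges
  grounded <- basal
  repeat {
    new <- grounded
    reach <- grounded[ri]                  # links whose resource is grounded
    new[unique(ci[reach])] <- TRUE
    if (identical(new, grounded)) break
    grounded <- new
  }
  if (!all(grounded))
    warning("trophic level undefined for node(s) with no path to a basal ",
            "resource: ", paste(nodes[!grounded], collapse = ", "))

  ## resources with undefined TL are excluded from a consumer's prey average
  W <- matrix(0, n, n)
  keep <- grounded[ci] & grounded[ri]
  nres_g <- tabulate(ci[keep], nbins = n)
  if (any(keep))
    W[cbind(ci[keep], ri[keep])] <- 1 / nres_g[ci[keep]]
  tl <- rep(NA_real_, n)
  idx <- which(grounded)
  A <- diag(length(idx)) - W[idx, idx, drop = FALSE]
  sol <- tryCatch(solve(A, rep(1, length(idx))), error = function(e) NULL)
  if (is.null(sol)) {
    ## damped fixed-point fallback for near-singular systems
    x <- rep(1, length(idx))
    for (it in seq_len(100000)) {
      x_new <- 0.5 * (1 + W[idx, idx, drop = FALSE] %*% x) + 0.5 * x
      if (max(abs(x_new - x)) < 1e-10) break
      x <- x_new
    }
    sol <- as.numeric(x_new)
  }
  tl[idx] <- as.numeric(sol)
  stats::setNames(tl, nodes)
}

#' Classify nodes as basal, intermediate or top, with diet flags
#'
#' Basal nodes have no resources; top nodes have no consumers; intermediate
#' nodes have both (self-links are ignored for this classification). An
#' isolated node is classified basal - a resource without consumers in a
#' given month remains a resource - and reported via a message. A node is
#' flagged cannibal if it has a self-link, and omnivore if it consumes
#' resources at two or more distinct integer-rounded trophic levels.
#'
#' @param web a [monthly_web()].
#' @param tl optional precomputed [trophic_levels()].
#' @return data.frame with columns `node`, `class` (basal / intermediate /
#'   top), `omnivore`, `cannibal`.
#' @export
trophic_positions <- function(web, tl = NULL) {
  stopifnot(inherits(web, "monthly_web"))
  nodes <- web$nodes
  lk <- web$links
  self <- if (nrow(lk)) lk$resource == lk$consumer else logical(0)
  cannibal <- nodes %in% lk$resource[self]
  lk <- lk[!self, , drop = FALSE]
  nres <- tabulate(match(lk$consumer, nodes), nbins = length(nodes))
  ncons <- tabulate(match(lk$resource, nodes), nbins = length(nodes))
  class <- ifelse(nres == 0, "basal",
                  ifelse(ncons == 0, "top", "intermediate"))
  iso <- nres == 0 & ncons == 0
  if (any(iso))
    message(sum(iso), " isolated node(s) classified basal")
  if (is.null(tl)) tl <- suppressWarnings(trophic_levels(web))
  omnivore <- vapply(nodes, function(n) {
    res <- lk$resource[lk$consumer == n]
    lev <- round(tl[res])
    length(unique(lev[!is.na(lev)])) >= 2
  }, logical(1))
  data.frame(node = nodes, class = class, omnivore = unname(omnivore),
             cannibal = cannibal, stringsAsFactors = FALSE)
}

#' The qualitative descriptor panel for one monthly web
#'
#' Computes the default panel of qualitative network descriptors: node and
#' link counts (S, L), link density (L/S) and connectance (L/S^2), the
#' fractions of top / intermediate / basal species, the fractions of
#' omnivores and cannibals, mean and SD of standardized generality
#' (resources per consumer divided by link density) and vulnerability
#' (consumers per resource divided by link density), mean and maximum
#' prey-averaged trophic level, and characteristic path length and mean
#' clustering coefficient of the undirected simple projection. Path length
#' is averaged over reachable pairs only; clustering is averaged over nodes
#' of degree >= 2 (0 when there are none).
#'
#' @param web a [monthly_web()].
#' @return Named numeric vector with elements `S`, `L`, `LD`, `C`,
#'   `frac_top`, `frac_intermediate`, `frac_basal`, `frac_omnivore`,
#'   `frac_cannibal`, `gen_mean`, `gen_sd`, `vul_mean`, `vul_sd`,
#'   `mean_TL`, `max_TL`, `cpl`, `cc`.
#' @export
descriptor_vector <- function(web) {
  stopifnot(inherits(web, "monthly_web"))
  S <- length(web$nodes)
  L <- nrow(web$links)
  LD <- link_density(S, L)
  tl <- suppressWarnings(trophic_levels(web))
  pos <- suppressMessages(trophic_positions(web, tl))

  lk <- web$links
  nres <- tabulate(match(lk$consumer, web$nodes), nbins = S)
  ncons <- tabulate(match(lk$resource, web$nodes), nbins = S)
  gen <- nres[nres > 0] / LD
  vul <- ncons[ncons > 0] / LD
  sd0 <- function(x) if (length(x) >= 2) stats::sd(x) else 0
  mean0 <- function(x) if (length(x)) mean(x) else 0

  g <- igraph::graph_from_data_frame(
    if (L) lk[, c("resource", "consumer")] else
      data.frame(resource = character(), consumer = character()),
    directed = FALSE, vertices = data.frame(name = web$nodes))
  g <- igraph::simplify(g)
  cpl <- suppressWarnings(igraph::mean_distance(g, unconnected = TRUE))
  if (!is.finite(cpl)) cpl <- NA_real_
  tr <- igraph::transitivity(g, type = "local")
  tr <- tr[!is.nan(tr) & !is.na(tr)]
  cc <- if (length(tr)) mean(tr) else 0

  c(S = S, L = L, LD = LD, C = connectance(S, L),
    frac_top = mean(pos$class == "top"),
    frac_intermediate = mean(pos$class == "intermediate"),
    frac_basal = mean(pos$class == "basal"),
    frac_omnivore = mean(pos$omnivore),
    frac_cannibal = mean(pos$cannibal),
    gen_mean = mean0(gen), gen_sd = sd0(gen),
    vul_mean = mean0(vul), vul_sd = sd0(vul),
    mean_TL = mean(tl, na.rm = TRUE), max_TL = max(tl, na.rm = TRUE),
    cpl = cpl, cc = cc)
}

#' Descriptor matrix for a year of monthly webs
#'
#' @param webs list of 12 [monthly_web()] objects (see
#'   [build_monthly_webs()]).
#' @return data.frame, one row per month (named by month abbreviation), one
#'   column per descriptor.
#' @export
descriptor_matrix <- function(webs) {
  rows <- lapply(webs, descriptor_vector)
  dm <- as.data.frame(do.call(rbind, rows))
  rownames(dm) <- month.abb[vapply(webs, function(w) w$month, integer(1))]
  dm
}
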