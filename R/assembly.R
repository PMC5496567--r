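## Idealized-year assembly: collapse incomplete multi-year records into one
## representative 12-month series, then realise a binary web per month.

#' Pool multi-year records into an idealized averaged year
#'
#' Species composition is pooled across years (a taxon is present in
#' idealized month m if it was recorded in month m of any year), and
#' abundances are averaged across years per (taxon, month). Months that no
#' sampling year covered for a group (e.g. a bimonthly fish cadence) would
#' otherwise drop the whole group from that month's web; when `gap_fill` is
#' `TRUE` such months inherit the group's presence and mean abundances from
#' the nearest sampled month within the same calendar season, and each
#' inheritance is recorded in the `gap_filled` table and raised as a
#' warning.
#'
#' @param samples sample-record table (see [read_samples()]).
#' @param gap_fill fill group-level coverage gaps from the nearest sampled
#'   month in the same season?
#' @param winter_months months treated as the cool season when choosing the
#'   gap-fill source (calendar convention only; the analysis stages derive
#'   their seasons from the data).
#' @return An object of class `idealized_year`: list with `presence`
#'   (taxa x 12 logical matrix), `abundance` (taxa x 12 mean abundances,
#'   `NA` where absent), `group` (named vector), `months_sampled` (per
#'   group) and `gap_filled` (data.frame group/month/source_month).
#' @export
pool_idealized_year <- function(samples, gap_fill = TRUE,
                                winter_months = 5:9) {
  samples <- validate_samples(samples)
  if (nrow(samples) == 0) stop("no sample records to pool")
  ids <- sort(unique(samples$taxon_id))
  grp <- samples$group[match(ids, samples$taxon_id)]
  names(grp) <- ids
  pres <- matrix(FALSE, length(ids), 12, dimnames = list(ids, NULL))
  ab <- matrix(NA_real_, length(ids), 12, dimnames = list(ids, NULL))
  agg <- stats::aggregate(abundance ~ taxon_id + month, data = samples,
                          FUN = mean)
  idx <- cbind(match(agg$taxon_id, ids), agg$month)
  pres[idx] <- TRUE
  ab[idx] <- agg$abundance

  months_sampled <- lapply(split(samples$month, samples$group),
                           function(m) sort(unique(m)))
  gap_filled <- data.frame(group = character(), month = integer(),
                           source_month = integer(), stringsAsFactors = FALSE)
  if (gap_fill) {
    for (g in names(months_sampled)) {
      covered <- months_sampled[[g]]
      gaps <- setdiff(1:12, covered)
      for (m in gaps) {
        same_season <- covered[(covered %in% winter_months) ==
                                 (m %in% winter_months)]
        cand <- if (length(same_season)) same_season else covered
        dist <- pmin(abs(cand - m), 12 - abs(cand - m))
        src <- cand[which.min(dist)]
        rows <- which(grp == g)
        pres[rows, m] <- pres[rows, src]
        ab[rows, m] <- ab[rows, src]
        gap_filled <- rbind(gap_filled,
                            data.frame(group = g, month = m,
                                       source_month = src,
                                       stringsAsFactors = FALSE))
      }
    }
    if (nrow(gap_filled))
      warning("filled ", nrow(gap_filled),
              " group-month coverage gap(s) from nearest sampled month ",
              "in the same season")
  }
  structure(list(presence = pres, abundance = ab, group = grp,
                 months_sampled = months_sampled, gap_filled = gap_filled),
            class = "idealized_year")
}

#' @export
print.idealized_year <- function(x, ...) {
  cat(sprintf("Idealized year: %d taxa, %d groups; monthly richness %s\n",
              nrow(x$presence), length(unique(x$group)),
              paste(colSums(x$presence), collapse = " ")))
  invisible(x)
}

#' Build the binary food web for one idealized month
#'
#' Nodes are the taxa present in the pooled month plus any basal-resource
#' taxa (permanent nodes); links are the cumulative links whose two
#' endpoints are both in the node set. The web is qualitative: no weights.
#'
#' @param iy an [pool_idealized_year()] result.
#' @param links cumulative link table (consumer, resource, origin).
#' @param month month 1-12.
#' @param taxa optional taxon table; its `basal_resource` rows are injected
#'   as permanent nodes.
#' @return A [monthly_web()].
#' @export
build_monthly_web <- function(iy, links, month, taxa = NULL) {
  stopifnot(inherits(iy, "idealized_year"))
  month <- as.integer(month)
  if (month < 1 || month > 12) stop("month must be in 1-12")
  nodes <- rownames(iy$presence)[iy$presence[, month]]
  if (!is.null(taxa))
    nodes <- union(nodes, taxa$id[taxa$group == "basal_resource"])
  keep <- links$resource %in% nodes & links$consumer %in% nodes
  lk <- links[keep, , drop = FALSE]
  monthly_web(month, nodes,
              data.frame(resource = lk$resource, consumer = lk$consumer,
                         origin = if ("origin" %in% names(lk)) lk$origin
                                  else NA_character_,
                         stringsAsFactors = FALSE))
}

#' Build all 12 monthly webs
#'
#' @inheritParams build_monthly_web
#' @return List of 12 [monthly_web()] objects, named by month abbreviation.
#' @export
build_monthly_webs <- function(iy, links, taxa = NULL) {
  webs <- lapply(1:12, function(m) build_monthly_web(iy, links, m, taxa))
  names(webs) <- month.abb
  webs
}

#' Fraction of a web's links that come from gut content analysis
#'
#' @param web a [monthly_web()] whose links carry an `origin` column.
#' @return Number in \[0, 1\], or `NA` with a warning for a zero-link web.
#' @export
gut_link_fraction <- function(web) {
  stopifnot(inherits(web, "monthly_web"))
  if (nrow(web$links) == 0) {
    warning("zero-link web: gut link fraction undefined")
    return(NA_real_)
  }
  if (!"origin" %in% names(web$links))
    stop("web links carry no origin labels")
  mean(web$links$origin == "gut_content")
}

#' Node and link counts for a list of monthly webs
#'
#' @param webs list of [monthly_web()] objects.
#' @return data.frame with columns `month`, `S`, `L`.
#' @export
web_sizes <- function(webs) {
  data.frame(month = vapply(webs, function(w) w$month, integer(1)),
             S = vapply(webs, function(w) length(w$nodes), integer(1)),
             L = vapply(webs, function(w) nrow(w$links), integer(1)),
             row.names = NULL)
}
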