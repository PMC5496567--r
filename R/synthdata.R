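## Synthetic community generator.
##
## Emulates the situation the assembly stage is designed for: a multi-year
## monitoring programme in which the four sampled groups were surveyed over
## different, only partially overlapping windows, insect-dominated groups
## thin out during the austral winter, and the cumulative diet knowledge
## forms a layered "master" web from which each month realises the sub-web
## of co-present taxa.

#' Configuration for the synthetic community generator
#'
#' Defaults encode the study conditions the generator emulates: group
#' richness around 40 macroinvertebrate, 25 phytoplankton, 10 zooplankton
#' and 10 fish taxa plus 4 permanent basal resources; austral winter months
#' May-September; a macroinvertebrate winter-absence probability of 0.3
#' (univoltine insects with terrestrial adult stages) against 0.05 for the
#' other groups; and 42% of realised links labelled as coming from gut
#' content analysis.
#'
#' @param seed integer seed; the same seed reproduces identical output.
#' @param richness named vector of mean taxon counts per sampled group.
#' @param n_basal number of permanent basal resource nodes.
#' @param winter_months integer vector of austral winter months.
#' @param p_absent_winter named per-group probability that a taxon is absent
#'   from every winter month.
#' @param p_absent_month probability that a taxon is missing from any single
#'   month of its schedule, emulating month-to-month turnover and imperfect
#'   detection.
#' @param links_per_consumer target expected number of resources per
#'   consumer in the master web.
#' @param p_cannibal probability that a macroinvertebrate or fish consumer
#'   carries a cannibalistic self-link.
#' @param gut_fraction fraction of links labelled `gut_content`.
#' @param years calendar years spanned by the simulated monitoring.
#' @param windows per-group sampling windows: each a list with `start` and
#'   `end` as `c(year, month)` and a month `cadence` (1 = monthly,
#'   2 = bimonthly).
#' @param season_abundance_ratio named per-group summer:winter ratio of mean
#'   abundance.
#' @param sdlog lognormal shape parameter for abundance noise.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         richness = c(phytoplankton = 25, zooplankton = 10,
                                      macroinvertebrate = 40, fish = 10),
                         n_basal = 4,
                         winter_months = 5:9,
                         p_absent_winter = c(phytoplankton = 0.05,
                                             zooplankton = 0.05,
                                             macroinvertebrate = 0.3,
                                             fish = 0.05),
                         p_absent_month = 0.10,
                         links_per_consumer = 12,
                         p_cannibal = 0.05,
                         gut_fraction = 0.42,
                         years = 2008:2014,
                         windows = NULL,
                         season_abundance_ratio = c(phytoplankton = 1,
                                                    zooplankton = 1.3,
                                                    macroinvertebrate = 1,
                                                    fish = 1.8),
                         sdlog = 0.4) {
  if (is.null(windows)) {
    windows <- list(
      phytoplankton     = list(start = c(2009, 7), end = c(2014, 3), cadence = 1),
      zooplankton       = list(start = c(2011, 4), end = c(2012, 3), cadence = 1),
      macroinvertebrate = list(start = c(2008, 3), end = c(2009, 4), cadence = 1),
      fish              = list(start = c(2008, 4), end = c(2012, 4), cadence = 2))
  }
  cfg <- list(seed = as.integer(seed), richness = richness, n_basal = n_basal,
              winter_months = as.integer(winter_months),
              p_absent_winter = p_absent_winter,
              p_absent_month = p_absent_month,
              links_per_consumer = links_per_consumer,
              p_cannibal = p_cannibal,
              gut_fraction = gut_fraction, years = years, windows = windows,
              season_abundance_ratio = season_abundance_ratio, sdlog = sdlog)
  probs <- c(cfg$p_absent_winter, cfg$p_absent_month, cfg$p_cannibal,
             cfg$gut_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(!cfg$winter_months %in% 1:12))
    stop("winter_months must be months 1-12")
  for (g in names(cfg$windows)) {
    w <- cfg$windows[[g]]
    if (!w$start[1] %in% cfg$years || !w$end[1] %in% cfg$years)
      stop("sampling window for ", g, " falls outside the simulated years")
  }
  class(cfg) <- "synth_config"
  cfg
}

## Run expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Feasible resource groups per consumer group. `lower` marks the strictly
## lower layers from which every consumer is guaranteed at least one
## resource, so that each consumer has a path to a basal node. Fish are
## never resources of zooplankton; within-group predation is feasible for
## macroinvertebrates and fish; self-links are handled separately (see
## `p_cannibal`).
.lw_diet_rules <- function() {
  list(
    zooplankton = list(
      allowed = c("basal_resource", "phytoplankton"),
      lower   = c("basal_resource", "phytoplankton")),
    macroinvertebrate = list(
      allowed = c("basal_resource", "phytoplankton", "zooplankton",
                  "macroinvertebrate"),
      lower   = c("basal_resource", "phytoplankton", "zooplankton")),
    fish = list(
      allowed = c("phytoplankton", "zooplankton", "macroinvertebrate",
                  "fish"),
      lower   = c("phytoplankton", "zooplankton", "macroinvertebrate")))
}

#' Generate the layered master food web
#'
#' Draws taxa for every group and a cumulative link set respecting trophic
#' layering: basal resources are eaten by zooplankton and
#' macroinvertebrates; phytoplankton by zooplankton, macroinvertebrates and
#' fish; zooplankton and macroinvertebrates by macroinvertebrates and fish;
#' fish only by other fish. Within-group predation is allowed in
#' macroinvertebrates and fish, cannibalistic self-links arise with
#' probability `p_cannibal`, and a fish can never be a zooplankter's
#' resource. Every consumer receives at least one resource from a strictly
#' lower layer, so prey-averaged trophic levels are always defined.
#'
#' @param cfg a [synth_config()].
#' @return List with `taxa` (taxon table; macroinvertebrate rows carry a
#'   logical `gut_model` flag marking chironomid-like taxa whose diets would
#'   come from gut contents) and `links` (consumer/resource data.frame,
#'   origin unset).
#' @export
generate_master_web <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    basal_names <- c("detritus", "periphyton", "macrophytes", "sediment_om",
                     paste0("basal_", seq_len(max(0, cfg$n_basal - 4))))
    basal <- data.frame(id = basal_names[seq_len(cfg$n_basal)],
                        group = "basal_resource", stringsAsFactors = FALSE)
    grp_tag <- c(phytoplankton = "phy", zooplankton = "zoo",
                 macroinvertebrate = "mac", fish = "fis")
    tabs <- list(basal)
    for (g in names(cfg$richness)) {
      n <- as.integer(round(cfg$richness[[g]]))
      if (n < 1) next
      tabs[[g]] <- data.frame(id = sprintf("%s_%02d", grp_tag[[g]], seq_len(n)),
                              group = g, stringsAsFactors = FALSE)
    }
    taxa <- do.call(rbind, tabs)
    rownames(taxa) <- NULL
    taxa$name <- taxa$id
    taxa$resolution <- ifelse(taxa$group == "basal_resource", "other", "species")
    ## chironomid-like macroinvertebrates: diets resolvable by gut contents
    taxa$gut_model <- FALSE
    mac <- which(taxa$group == "macroinvertebrate")
    if (length(mac)) {
      n_chir <- ceiling(0.3 * length(mac))
      taxa$gut_model[mac[seq_len(n_chir)]] <- TRUE
      taxa$name[mac[seq_len(n_chir)]] <-
        sprintf("chironomid_sp_%02d", seq_len(n_chir))
    }
    taxa$gut_model[taxa$group == "fish"] <- TRUE
    taxa <- validate_taxa(taxa)

    rules <- .lw_diet_rules()
    cons <- taxa[taxa$group %in% names(rules), , drop = FALSE]
    out <- vector("list", nrow(cons))
    for (i in seq_len(nrow(cons))) {
      g <- cons$group[i]
      allowed <- setdiff(taxa$id[taxa$group %in% rules[[g]]$allowed],
                         cons$id[i])
      lower <- taxa$id[taxa$group %in% rules[[g]]$lower]
      if (cfg$links_per_consumer > length(allowed))
        stop("infeasible link density target: ", cfg$links_per_consumer,
             " links per consumer but only ", length(allowed),
             " feasible resources for group ", g)
      d <- stats::rbinom(1, length(allowed),
                         cfg$links_per_consumer / length(allowed))
      d <- max(1L, d)
      first <- if (length(lower) == 1) lower else sample(lower, 1)
      rest <- setdiff(allowed, first)
      res <- c(first, if (d > 1 && length(rest))
        rest[sample.int(length(rest), min(d - 1, length(rest)))])
      if (g %in% c("macroinvertebrate", "fish") &&
          stats::runif(1) < cfg$p_cannibal)
        res <- c(res, cons$id[i])
      out[[i]] <- data.frame(consumer = cons$id[i], resource = res,
                             stringsAsFactors = FALSE)
    }
    links <- do.call(rbind, out)
    rownames(links) <- NULL
    list(taxa = taxa, links = links)
  })
}

.month_seq <- function(start, end, cadence) {
  ## sequence of (year, month) pairs at the given month cadence
  from <- start[1] * 12 + (start[2] - 1)
  to <- end[1] * 12 + (end[2] - 1)
  idx <- seq(from, to, by = cadence)
  data.frame(year = idx %/% 12, month = idx %% 12 + 1)
}

#' Generate sample records and the ground-truth presence schedule
#'
#' Each non-basal taxon gets a presence schedule: with the group's
#' `p_absent_winter` probability it is absent from all winter months
#' (mimicking insect taxa with terrestrial adult stages), and independently
#' each remaining month is dropped with probability `p_absent_month`
#' (month-to-month turnover). Basal resources are always present and never
#' sampled. Abundances are lognormal with a group-level summer multiplier
#' (`season_abundance_ratio`); records are emitted only inside each group's
#' sampling window, at its cadence.
#'
#' @param cfg a [synth_config()].
#' @param master output of [generate_master_web()].
#' @return List with `samples` (taxon_id, group, year, month, abundance) and
#'   `truth_presence` (taxon_id, month, present) covering all taxa including
#'   basal resources.
#' @export
generate_samples <- function(cfg, master) {
  stopifnot(inherits(cfg, "synth_config"))
  taxa <- master$taxa
  with_seed(cfg$seed + 1L, {
    pres <- matrix(TRUE, nrow = nrow(taxa), ncol = 12,
                   dimnames = list(taxa$id, NULL))
    sampled <- taxa$group != "basal_resource"
    for (i in which(sampled)) {
      g <- taxa$group[i]
      if (stats::runif(1) < cfg$p_absent_winter[[g]])
        pres[i, cfg$winter_months] <- FALSE
      on_months <- which(pres[i, ])
      drop <- on_months[stats::runif(length(on_months)) < cfg$p_absent_month]
      pres[i, drop] <- FALSE
      if (!any(pres[i, ])) pres[i, sample(setdiff(1:12, cfg$winter_months), 1)] <- TRUE
    }

    base_meanlog <- stats::rnorm(nrow(taxa), meanlog_by_group(taxa$group), 1)
    recs <- list()
    for (g in names(cfg$windows)) {
      w <- cfg$windows[[g]]
      ym <- .month_seq(w$start, w$end, w$cadence)
      gi <- which(taxa$group == g)
      for (k in seq_len(nrow(ym))) {
        m <- ym$month[k]
        here <- gi[pres[gi, m]]
        if (!length(here)) next
        mult <- if (m %in% cfg$winter_months) 1
                else cfg$season_abundance_ratio[[g]]
        ab <- stats::rlnorm(length(here),
                            meanlog = base_meanlog[here] + log(mult),
                            sdlog = cfg$sdlog)
        recs[[length(recs) + 1L]] <-
          data.frame(taxon_id = taxa$id[here], group = g, year = ym$year[k],
                     month = m, abundance = ab, stringsAsFactors = FALSE)
      }
    }
    samples <- do.call(rbind, recs)
    rownames(samples) <- NULL
    truth <- data.frame(taxon_id = rep(taxa$id, each = 12),
                        month = rep(1:12, times = nrow(taxa)),
                        present = as.vector(t(pres)),
                        stringsAsFactors = FALSE)
    list(samples = validate_samples(samples), truth_presence = truth)
  })
}

## typical log-abundance by group (plankton dense, fish sparse)
meanlog_by_group <- function(group) {
  c(basal_resource = 0, phytoplankton = log(500), zooplankton = log(50),
    macroinvertebrate = log(20), fish = log(3))[group]
}

#' Label link origins (gut content vs literature)
#'
#' Assigns each master-web link an origin label. Links whose consumer is a
#' fish or a chironomid-like macroinvertebrate (the taxa whose diets a field
#' study would resolve by gut content analysis) are labelled `gut_content`
#' with twice the base odds; labelling probabilities are scaled so the
#' expected overall gut fraction equals `cfg$gut_fraction`.
#'
#' @param links master link table (consumer, resource).
#' @param cfg a [synth_config()].
#' @param taxa taxon table carrying the `gut_model` flag.
#' @return The link table with an `origin` column.
#' @export
label_link_origin <- function(links, cfg, taxa) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 2L, {
    gut_consumers <- taxa$id[taxa$gut_model %in% TRUE]
    w <- ifelse(links$consumer %in% gut_consumers, 2, 1)
    ## water-filling: p_i proportional to w_i, capped at 1, with the scale
    ## chosen so the expected overall gut fraction equals gut_fraction
    target <- cfg$gut_fraction * length(w)
    sc <- target / sum(w)
    repeat {
      p <- pmin(1, sc * w)
      if (abs(sum(p) - target) < 1e-9 || all(p >= 1)) break
      free <- p < 1
      sc_new <- (target - sum(p[!free])) / sum(w[free])
      if (!is.finite(sc_new) || abs(sc_new - sc) < 1e-12) break
      sc <- sc_new
    }
    links$origin <- ifelse(stats::runif(nrow(links)) < p,
                           "gut_content", "literature")
    links
  })
}

#' Generate monthly environmental measurements
#'
#' A representative standardized year for a subtropical lake: water
#' temperature peaks in the austral summer (~26 degrees C in January and
#' February) and bottoms out in winter (~16 degrees C), dissolved oxygen
#' moves inversely with temperature, chlorophyll a tracks the phytoplankton
#' growing season, and alkalinity is aseasonal. Small lognormal noise is
#' added to each monthly value.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns `variable`, `month`, `value`.
#' @export
generate_environment <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 3L, {
    m <- 1:12
    seasonal <- cos(2 * pi * (m - 1.5) / 12)   # peak mid-January/February
    vals <- rbind(
      data.frame(variable = "water_temperature", month = m,
                 value = 21 + 5 * seasonal + stats::rnorm(12, 0, 0.4)),
      data.frame(variable = "dissolved_oxygen", month = m,
                 value = 8 - 1.2 * seasonal + stats::rnorm(12, 0, 0.15)),
      data.frame(variable = "chlorophyll_a", month = m,
                 value = pmax(0.5, 6 + 3 * seasonal + stats::rnorm(12, 0, 0.5))),
      data.frame(variable = "alkalinity", month = m,
                 value = 250 + stats::rnorm(12, 0, 8)))
    vals
  })
}

#' Generate a complete synthetic community dataset
#'
#' Convenience wrapper running [generate_master_web()],
#' [generate_samples()], [label_link_origin()] and
#' [generate_environment()] under one configuration.
#'
#' @param cfg a [synth_config()].
#' @return List with `taxa`, `links` (with origins), `samples`,
#'   `truth_presence` and `environment`.
#' @export
generate_community <- function(cfg = synth_config()) {
  master <- generate_master_web(cfg)
  sam <- generate_samples(cfg, master)
  links <- label_link_origin(master$links, cfg, master$taxa)
  env <- generate_environment(cfg)
  list(taxa = master$taxa, links = links, samples = sam$samples,
       truth_presence = sam$truth_presence, environment = env)
}

#' Write a synthetic dataset to CSV files
#'
#' Emits `taxa.csv`, `samples.csv`, `links.csv`, `environment.csv` and
#' `truth_presence.csv` into `dir`.
#'
#' @param community output of [generate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(community$taxa, file.path(dir, "taxa.csv"),
                   row.names = FALSE)
  s <- community$samples
  names(s)[names(s) == "taxon_id"] <- "taxon"
  utils::write.csv(s, file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(community$links, file.path(dir, "links.csv"),
                   row.names = FALSE)
  utils::write.csv(community$environment, file.path(dir, "environment.csv"),
                   row.names = FALSE)
  utils::write.csv(community$truth_presence,
                   file.path(dir, "truth_presence.csv"), row.names = FALSE)
  invisible(dir)
}
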