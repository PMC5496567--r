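## End-to-end orchestration: synthesise or ingest -> assemble -> descriptor
## panel -> diversity -> ordination + envfit -> link-pattern topology ->
## seasonal contrasts, under one configuration and one seed.

LW_SUMMARY_SCHEMA <- "lakeweb-summary-1"

#' Pipeline configuration
#'
#' Stochastic defaults follow the analysis conventions the package
#' implements: 100 NMDS restarts, 1,000 envfit permutations and 4,000
#' posterior draws.
#'
#' @param seed master seed; each stage derives its own stream from it, so
#'   stages are individually reproducible.
#' @param synth a [synth_config()] used when no input `paths` are given.
#' @param paths optional named list of CSV paths (`samples`, `links`,
#'   `taxa`, `environment`) to run on real data instead of synthetic.
#' @param nmds_restarts,envfit_perm,posterior_draws stochastic settings.
#' @param descriptors descriptor subset used for ordination and contrasts
#'   (default: the full panel of [descriptor_vector()]).
#' @param clustering_method linkage for [extract_seasons()].
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, synth = synth_config(seed = seed),
                       paths = NULL, nmds_restarts = 100,
                       envfit_perm = 1000, posterior_draws = 4000,
                       descriptors = NULL, clustering_method = "average") {
  structure(list(seed = as.integer(seed), synth = synth, paths = paths,
                 nmds_restarts = nmds_restarts, envfit_perm = envfit_perm,
                 posterior_draws = posterior_draws, descriptors = descriptors,
                 clustering_method = clustering_method),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `synth` block is
#' passed to [synth_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synth %||% list()
  if (!is.null(y$seed) && is.null(syn_args$seed)) syn_args$seed <- y$seed
  if (!is.null(syn_args$winter_months))
    syn_args$winter_months <- as.integer(syn_args$winter_months)
  for (nm in c("richness", "p_absent_winter", "season_abundance_ratio"))
    if (!is.null(syn_args[[nm]])) syn_args[[nm]] <- unlist(syn_args[[nm]])
  run_config(seed = y$seed %||% 1,
             synth = do.call(synth_config, syn_args),
             paths = y$paths,
             nmds_restarts = y$nmds_restarts %||% 100,
             envfit_perm = y$envfit_perm %||% 1000,
             posterior_draws = y$posterior_draws %||% 4000,
             descriptors = y$descriptors,
             clustering_method = y$clustering_method %||% "average")
}

## deterministic per-stage seed derived from the master seed and stage name
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 997L + sum(utf8ToInt(stage)) * 131L) %% 2147483647L
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full seasonal food-web pipeline
#'
#' Executes every stage and returns all intermediate products plus a
#' machine-readable summary. With an `outdir`, artifacts are written as
#' CSV (webs, descriptor matrix, diversity table, ordination scores, envfit
#' table, similarity matrix, season assignment, link partition, contrasts)
#' and the summary as JSON. Two runs with the same configuration produce
#' identical summaries.
#'
#' @param cfg a [run_config()].
#' @param outdir optional output directory.
#' @return List with `community`, `iy`, `webs`, `descriptors`, `diversity`,
#'   `ordination`, `envfit`, `similarity`, `seasons`, `seasons_nmds`,
#'   `link_partition`, `contrasts` and `summary`.
#' @export
run_all <- function(cfg = run_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))

  community <- .stage("ingest", {
    if (!is.null(cfg$paths)) {
      missing_files <- unlist(cfg$paths)[!file.exists(unlist(cfg$paths))]
      if (length(missing_files))
        stop("missing input file(s): ", paste(missing_files, collapse = ", "))
      taxa <- if (!is.null(cfg$paths$taxa))
        validate_taxa(utils::read.csv(cfg$paths$taxa,
                                      stringsAsFactors = FALSE))
      list(taxa = taxa,
           links = read_links(cfg$paths$links, taxa = taxa),
           samples = read_samples(cfg$paths$samples),
           truth_presence = NULL,
           environment = if (!is.null(cfg$paths$environment))
             read_environment(cfg$paths$environment))
    } else {
      syn <- cfg$synth
      syn$seed <- .stage_seed(cfg$seed, "synth")
      generate_community(syn)
    }
  })

  winter_cal <- if (!is.null(cfg$synth)) cfg$synth$winter_months else 5:9
  iy <- .stage("assemble", suppressWarnings(
    pool_idealized_year(community$samples, winter_months = winter_cal)))
  webs <- .stage("assemble",
                 build_monthly_webs(iy, community$links, community$taxa))
  sizes <- web_sizes(webs)

  dm <- .stage("metrics", descriptor_matrix(webs))
  dm_used <- if (is.null(cfg$descriptors)) dm else dm[, cfg$descriptors]

  div <- .stage("diversity",
                diversity_table(iy, n_draws = cfg$posterior_draws,
                                seed = .stage_seed(cfg$seed, "diversity")))

  ord <- .stage("ordinate",
    nmds(bray_curtis(wisconsin(prepare_descriptors(dm_used))), k = 2,
         n_restarts = cfg$nmds_restarts,
         seed = .stage_seed(cfg$seed, "ordinate")))

  fits <- .stage("envfit", {
    vars <- NULL
    if (!is.null(community$environment))
      vars <- environment_matrix(community$environment)
    dens <- sapply(setdiff(sort(unique(iy$group)), "basal_resource"),
                   function(g) {
      rows <- names(iy$group)[iy$group == g]
      colSums(iy$abundance[rows, , drop = FALSE], na.rm = TRUE)
    })
    colnames(dens) <- paste0("density_", colnames(dens))
    hm <- stats::reshape(div[, c("group", "month", "H_mean")],
                         idvar = "month", timevar = "group",
                         direction = "wide")
    hm <- as.matrix(hm[order(hm$month), -1, drop = FALSE])
    colnames(hm) <- sub("^H_mean\\.", "H_", colnames(hm))
    vars <- cbind(vars, dens, hm)
    keep <- apply(vars, 2, function(v) !anyNA(v) && length(unique(v)) > 1)
    envfit_table(ord, vars[, keep, drop = FALSE],
                 n_perm = cfg$envfit_perm,
                 seed = .stage_seed(cfg$seed, "envfit"))
  })

  sim <- .stage("topology", similarity_matrix(webs))
  seasons <- .stage("topology",
                    extract_seasons(sim, sizes$L,
                                    method = cfg$clustering_method))
  ## Ward linkage for the score-based clustering: ordination coordinates
  ## are Euclidean, where minimum-variance linkage is the standard choice
  ## and does not shear off single outlying months
  seasons_nmds <- .stage("topology",
                         extract_seasons(as.matrix(stats::dist(ord$scores)),
                                         sizes$L, method = "ward.D2",
                                         is_distance = TRUE))
  agreement <- season_agreement(seasons, seasons_nmds)
  parts <- .stage("topology", partition_links(webs, seasons))

  contrasts <- .stage("contrast", seasonal_contrasts(dm_used, seasons))

  gut <- vapply(webs, function(w) suppressWarnings(gut_link_fraction(w)),
                numeric(1))
  summary <- list(
    schema = LW_SUMMARY_SCHEMA,
    seed = cfg$seed,
    S_max = max(sizes$S), S_min = min(sizes$S),
    L_max = max(sizes$L), L_min = min(sizes$L),
    S_decrease_pct = 100 * (max(sizes$S) - min(sizes$S)) / max(sizes$S),
    L_decrease_pct = 100 * (max(sizes$L) - min(sizes$L)) / max(sizes$L),
    mean_connectance_pct = 100 * mean(dm$C),
    winter_months = unname(which(seasons$season[month.abb] == "winter")),
    summer_mean_L = mean(sizes$L[seasons$season == "summer"]),
    winter_mean_L = mean(sizes$L[seasons$season == "winter"]),
    L_increase_pct = 100 *
      (mean(sizes$L[seasons$season == "summer"]) -
         mean(sizes$L[seasons$season == "winter"])) /
      mean(sizes$L[seasons$season == "winter"]),
    gut_fraction_range = c(min(gut, na.rm = TRUE), max(gut, na.rm = TRUE)),
    stress = ord$stress, linear_R2 = ord$linear_R2,
    nonmetric_R2 = ord$nonmetric_R2,
    clustering_agreement = agreement,
    link_partition_sizes = lengths(parts))

  res <- list(community = community, iy = iy, webs = webs, descriptors = dm,
              diversity = div, ordination = ord, envfit = fits,
              similarity = sim, seasons = seasons,
              seasons_nmds = seasons_nmds, link_partition = parts,
              contrasts = contrasts, summary = summary)

  if (!is.null(outdir)) .write_run(res, outdir)
  res
}

.write_run <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wdir <- file.path(outdir, "webs")
  if (!dir.exists(wdir)) dir.create(wdir)
  for (w in res$webs)
    write_web(w, file.path(wdir, sprintf("web_%02d.csv", w$month)))
  utils::write.csv(cbind(month = rownames(res$descriptors),
                         res$descriptors),
                   file.path(outdir, "descriptor_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(res$diversity, file.path(outdir, "diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(month = rownames(res$ordination$scores),
                         as.data.frame(res$ordination$scores)),
                   file.path(outdir, "ordination_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(res$envfit, file.path(outdir, "envfit.csv"),
                   row.names = FALSE)
  utils::write.csv(res$similarity, file.path(outdir, "similarity_matrix.csv"))
  utils::write.csv(data.frame(month = names(res$seasons$season),
                              season = unname(res$seasons$season)),
                   file.path(outdir, "season_assignment.csv"),
                   row.names = FALSE)
  lp <- do.call(rbind, lapply(names(res$link_partition), function(k)
    if (length(res$link_partition[[k]]))
      data.frame(link = res$link_partition[[k]], class = k,
                 stringsAsFactors = FALSE)))
  utils::write.csv(lp, file.path(outdir, "link_partition.csv"),
                   row.names = FALSE)
  utils::write.csv(res$contrasts$contrasts,
                   file.path(outdir, "contrasts.csv"), row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
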