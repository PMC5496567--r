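#' @keywords internal
"_PACKAGE"

## Closed set of functional groups used throughout the package.  Basal
## resources (detritus, periphyton, ...) are network nodes but are never
## sampled as organisms; the other four groups are the sampled communities.
LW_GROUPS <- c("basal_resource", "phytoplankton", "zooplankton",
               "macroinvertebrate", "fish")

LW_RESOLUTIONS <- c("species", "genus", "family", "other")

LW_ORIGINS <- c("gut_content", "literature")

#' Functional groups recognised by the package
#'
#' @return Character vector of the five functional groups: basal resources,
#'   phytoplankton, zooplankton, macroinvertebrates and fish.
#' @export
lakeweb_groups <- function() LW_GROUPS

## ---------------------------------------------------------------------------
## Taxon table
## ---------------------------------------------------------------------------

#' Construct and validate a taxon table
#'
#' A taxon table has one row per node of the food web: an identifier, a free
#' text name, a functional group from the closed set returned by
#' [lakeweb_groups()], and the taxonomic resolution of the identification.
#'
#' @param id character vector of unique taxon identifiers.
#' @param name free-text names (defaults to `id`).
#' @param group functional group, one of [lakeweb_groups()].
#' @param resolution one of `"species"`, `"genus"`, `"family"`, `"other"`.
#' @return A `data.frame` with columns `id`, `name`, `group`, `resolution`.
#' @export
taxon_table <- function(id, name = id, group, resolution = "species") {
  tab <- data.frame(id = as.character(id), name = as.character(name),
                    group = as.character(group),
                    resolution = as.character(resolution),
                    stringsAsFactors = FALSE)
  validate_taxa(tab)
}

#' @rdname taxon_table
#' @param taxa a candidate taxon table.
#' @export
validate_taxa <- function(taxa) {
  stopifnot(is.data.frame(taxa))
  need <- c("id", "group")
  miss <- setdiff(need, names(taxa))
  if (length(miss))
    stop("taxon table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(taxa$id))
    stop("duplicated taxon id(s): ",
         paste(unique(taxa$id[duplicated(taxa$id)]), collapse = ", "))
  bad <- !taxa$group %in% LW_GROUPS
  if (any(bad))
    stop("unknown functional group(s): ",
         paste(unique(taxa$group[bad]), collapse = ", "))
  if (!"name" %in% names(taxa)) taxa$name <- taxa$id
  if (!"resolution" %in% names(taxa)) taxa$resolution <- "other"
  taxa
}

## ---------------------------------------------------------------------------
## Sample records
## ---------------------------------------------------------------------------

#' Read long-format community samples from CSV
#'
#' Reads monthly abundance records (one row per taxon x year x month).
#' Abundance units are per-group conventions (individuals/ml for plankton,
#' individuals/0.5 m2 for macroinvertebrates, individuals/100 m2 for fish);
#' the package never mixes units across groups.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector mapping the roles
#'   `taxon`, `group`, `year`, `month`, `abundance` to column names in the
#'   file. Defaults to identically named columns.
#' @return A `data.frame` with columns `taxon_id`, `group`, `year`, `month`,
#'   `abundance`.
#' @export
read_samples <- function(path,
                         schema = c(taxon = "taxon", group = "group",
                                    year = "year", month = "month",
                                    abundance = "abundance")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss))
    stop("sample file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(taxon_id  = as.character(raw[[schema[["taxon"]]]]),
                    group     = as.character(raw[[schema[["group"]]]]),
                    year      = as.integer(raw[[schema[["year"]]]]),
                    month     = as.integer(raw[[schema[["month"]]]]),
                    abundance = as.numeric(raw[[schema[["abundance"]]]]),
                    stringsAsFactors = FALSE)
  validate_samples(out)
}

#' Validate a sample-record table
#'
#' Checks month range (1-12), non-negative abundances and known functional
#' groups; errors cite the offending row numbers.
#'
#' @param samples data.frame with columns `taxon_id`, `group`, `year`,
#'   `month`, `abundance`.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  need <- c("taxon_id", "group", "year", "month", "abundance")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  bad_month <- which(is.na(samples$month) | samples$month < 1 |
                       samples$month > 12)
  if (length(bad_month))
    stop("invalid month (must be 1-12) in row(s): ",
         paste(utils::head(bad_month, 10), collapse = ", "))
  bad_ab <- which(is.na(samples$abundance) | samples$abundance < 0)
  if (length(bad_ab))
    stop("negative or missing abundance in row(s): ",
         paste(utils::head(bad_ab, 10), collapse = ", "))
  bad_grp <- which(!samples$group %in% LW_GROUPS)
  if (length(bad_grp))
    stop("unknown functional group in row(s): ",
         paste(utils::head(bad_grp, 10), collapse = ", "))
  samples
}

## ---------------------------------------------------------------------------
## Link records
## ---------------------------------------------------------------------------

#' Read a consumer-resource link table
#'
#' Two dialects are supported. The default edge list is a CSV with columns
#' `consumer`, `resource` and optionally `origin` (`"gut_content"` or
#' `"literature"`; defaults to literature when absent). The `"matrix"`
#' dialect is a 0/1 adjacency table with resources as rows and consumers as
#' columns, the first column holding resource identifiers; nonzero cells
#' become links (all labelled literature).
#'
#' Duplicate (consumer, resource) pairs are collapsed to one record with a
#' warning. If `taxa` is supplied, links referencing unknown identifiers are
#' a referential-integrity error.
#'
#' @param path path to the CSV file.
#' @param format `"edgelist"` (default) or `"matrix"`.
#' @param taxa optional taxon table for referential-integrity checking.
#' @return data.frame with columns `consumer`, `resource`, `origin`.
#' @export
read_links <- function(path, format = c("edgelist", "matrix"), taxa = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("consumer", "resource"), names(raw))
    if (length(miss))
      stop("link file ", path, " is missing column(s): ",
           paste(miss, collapse = ", "))
    origin <- if ("origin" %in% names(raw)) as.character(raw$origin)
              else rep("literature", nrow(raw))
    origin[is.na(origin) | origin == ""] <- "literature"
    links <- data.frame(consumer = as.character(raw$consumer),
                        resource = as.character(raw$resource),
                        origin = origin, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    resources <- as.character(raw[[1]])
    consumers <- names(raw)[-1]
    m <- as.matrix(raw[, -1, drop = FALSE])
    idx <- which(m != 0, arr.ind = TRUE)
    links <- data.frame(consumer = consumers[idx[, 2]],
                        resource = resources[idx[, 1]],
                        origin = "literature", stringsAsFactors = FALSE)
  }
  validate_links(links, taxa = taxa)
}

#' Validate (and deduplicate) a link table
#'
#' @param links data.frame with columns `consumer`, `resource` and optional
#'   `origin`.
#' @param taxa optional taxon table; when given, every link endpoint must be
#'   a known taxon id.
#' @return The validated link table with unique (consumer, resource) pairs.
#' @export
validate_links <- function(links, taxa = NULL) {
  stopifnot(is.data.frame(links))
  miss <- setdiff(c("consumer", "resource"), names(links))
  if (length(miss))
    stop("link table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"origin" %in% names(links)) links$origin <- "literature"
  bad <- which(!links$origin %in% LW_ORIGINS)
  if (length(bad))
    stop("unknown link origin in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  key <- paste(links$resource, links$consumer, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(ndup, " duplicate (consumer, resource) pair(s) collapsed")
    links <- links[!duplicated(key), , drop = FALSE]
    rownames(links) <- NULL
  }
  if (!is.null(taxa)) {
    unknown <- setdiff(unique(c(links$consumer, links$resource)), taxa$id)
    if (length(unknown))
      stop("link(s) reference unknown taxon id(s): ",
           paste(utils::head(unknown, 10), collapse = ", "))
  }
  links
}

## ---------------------------------------------------------------------------
## Environmental records
## ---------------------------------------------------------------------------

#' Read monthly environmental measurements
#'
#' Expects columns `variable`, `month`, `value`; multiple values for the same
#' (variable, month) are averaged, producing one representative standardized
#' year.
#'
#' @param path path to a CSV file.
#' @return data.frame with one row per (variable, month).
#' @export
read_environment <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("variable", "month", "value"), names(raw))
  if (length(miss))
    stop("environment file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(raw$month < 1 | raw$month > 12))
    stop("environment months must be in 1-12")
  agg <- stats::aggregate(value ~ variable + month, data = raw, FUN = mean)
  agg <- agg[order(agg$variable, agg$month), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Reshape an environment table to a month-by-variable matrix
#'
#' @param env data.frame as returned by [read_environment()].
#' @return A 12 x n_variables numeric matrix, rows named by month.
#' @export
environment_matrix <- function(env) {
  vars <- sort(unique(env$variable))
  m <- matrix(NA_real_, nrow = 12, ncol = length(vars),
              dimnames = list(month.abb, vars))
  for (i in seq_len(nrow(env)))
    m[env$month[i], env$variable[i]] <- env$value[i]
  m
}

## ---------------------------------------------------------------------------
## Monthly webs
## ---------------------------------------------------------------------------

#' Construct a monthly binary food web
#'
#' A `monthly_web` holds the node set and the directed link set of one
#' month's qualitative web. Links are stored resource -> consumer, i.e. in
#' the direction of energy flow; every metric in the package states its
#' convention against this.
#'
#' @param month integer 1-12.
#' @param nodes character vector of taxon ids present this month.
#' @param links data.frame with columns `resource`, `consumer` (and any
#'   extra columns, e.g. `origin`); duplicates are dropped.
#' @return An object of class `monthly_web`.
#' @export
monthly_web <- function(month, nodes, links) {
  month <- as.integer(month)
  if (is.na(month) || month < 1 || month > 12)
    stop("month must be in 1-12")
  nodes <- unique(as.character(nodes))
  if (length(nodes) < 1) stop("a monthly web needs at least one node")
  if (is.null(links) || nrow(links) == 0) {
    links <- data.frame(resource = character(), consumer = character(),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("resource", "consumer") %in% names(links)))
    links$resource <- as.character(links$resource)
    links$consumer <- as.character(links$consumer)
    key <- paste(links$resource, links$consumer, sep = "\r")
    links <- links[!duplicated(key), , drop = FALSE]
    ends <- unique(c(links$resource, links$consumer))
    out <- setdiff(ends, nodes)
    if (length(out))
      stop("link endpoint(s) not in node set: ",
           paste(utils::head(out, 10), collapse = ", "))
    rownames(links) <- NULL
  }
  structure(list(month = month, nodes = nodes, links = links),
            class = "monthly_web")
}

#' @export
print.monthly_web <- function(x, ...) {
  cat(sprintf("Monthly food web (%s): S = %d nodes, L = %d links\n",
              month.abb[x$month], length(x$nodes), nrow(x$links)))
  invisible(x)
}

#' Link set of a web as "resource -> consumer" keys
#'
#' @param web a `monthly_web`.
#' @return Character vector of directed link keys.
#' @export
link_set <- function(web) {
  if (nrow(web$links) == 0) return(character())
  paste(web$links$resource, web$links$consumer, sep = " -> ")
}

#' Write / read a monthly web as plain CSV
#'
#' The file is a three-column CSV (`record`, `value1`, `value2`): one
#' `month` row, one `node` row per node, and one `link` row per directed
#' resource -> consumer pair. `read_web(write_web(w))` reproduces `w`
#' exactly (node and link sets; ordering is normalised).
#'
#' @param web a `monthly_web`.
#' @param path output (input) file path.
#' @return `write_web` returns `path` invisibly; `read_web` a `monthly_web`.
#' @export
write_web <- function(web, path) {
  stopifnot(inherits(web, "monthly_web"))
  df <- rbind(
    data.frame(record = "month", value1 = as.character(web$month),
               value2 = "", stringsAsFactors = FALSE),
    data.frame(record = "node", value1 = sort(web$nodes), value2 = "",
               stringsAsFactors = FALSE),
    if (nrow(web$links)) {
      o <- order(web$links$resource, web$links$consumer)
      data.frame(record = "link", value1 = web$links$resource[o],
                 value2 = web$links$consumer[o], stringsAsFactors = FALSE)
    })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_web
#' @export
read_web <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  month <- as.integer(df$value1[df$record == "month"][1])
  nodes <- df$value1[df$record == "node"]
  lk <- df[df$record == "link", , drop = FALSE]
  links <- data.frame(resource = lk$value1, consumer = lk$value2,
                      stringsAsFactors = FALSE)
  monthly_web(month, nodes, links)
}
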