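#' Read and validate a visit-log CSV
#'
#' The visit-log dialect is a CSV with header columns `timestamp`
#' (ISO 8601, second resolution), `tag_id`, `feeder_id`, `site_id`, and
#' `access` (0/1). Malformed rows — unparseable timestamps, access values
#' outside 0/1, empty identifiers, duplicate (timestamp, tag, feeder)
#' triples — are rejected with their line numbers; a missing column is
#' fatal.
#'
#' @param path Path to the CSV file.
#' @param origin Date of study day 1 (ISO string); internal times are
#'   seconds from `origin` 00:00 UTC.
#' @return Visit data.frame (`time`, `tag`, `feeder`, `site`, `access`,
#'   `day`) with attributes `counts` (total/kept/rejected) and `rejected`
#'   (data.frame `line`, `reason`).
#' @export
read_visit_log <- function(path, origin = "2021-01-04") {
  if (!file.exists(path)) stop("read_visit_log: file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  needed <- c("timestamp", "tag_id", "feeder_id", "site_id", "access")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("read_visit_log: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (!n) {
    out <- data.frame(time = numeric(), tag = character(),
                      feeder = character(), site = character(),
                      access = integer(), day = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "counts") <- c(total = 0L, kept = 0L, rejected = 0L)
    attr(out, "rejected") <- data.frame(line = integer(),
                                        reason = character())
    return(out)
  }
  origin_t <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  retry <- is.na(ts)
  if (any(retry)) {
    ts[retry] <- as.POSIXct(strptime(raw$timestamp[retry],
                                     "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  }
  reason <- rep(NA_character_, n)
  reason[is.na(ts)] <- "unparseable timestamp"
  bad_access <- !(raw$access %in% c("0", "1"))
  reason[is.na(reason) & bad_access] <- "access not in {0,1}"
  empty_id <- raw$tag_id == "" | raw$feeder_id == "" | raw$site_id == ""
  reason[is.na(reason) & empty_id] <- "empty identifier"
  key <- paste(raw$timestamp, raw$tag_id, raw$feeder_id)
  reason[is.na(reason) & duplicated(key)] <- "duplicate (timestamp, tag, feeder)"

  keep <- is.na(reason)
  rejected <- data.frame(line = which(!keep) + 1L,  # +1 for the header line
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(sprintf("read_visit_log: rejected %d of %d row(s)",
                    nrow(rejected), n))
  }
  time <- as.numeric(difftime(ts[keep], origin_t, units = "secs"))
  out <- data.frame(time = time, tag = raw$tag_id[keep],
                    feeder = raw$feeder_id[keep], site = raw$site_id[keep],
                    access = as.integer(raw$access[keep]),
                    day = floor(time / 86400) + 1L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$feeder, out$time), ]
  rownames(out) <- NULL
  attr(out, "counts") <- c(total = n, kept = sum(keep),
                           rejected = sum(!keep))
  attr(out, "rejected") <- rejected
  out
}

#' Write a visit stream in the visit-log CSV dialect
#'
#' @param visits Visit data.frame (`time`, `tag`, `feeder`, `site`,
#'   `access`).
#' @param path Output path.
#' @inheritParams read_visit_log
#' @return `path`, invisibly.
#' @export
write_visit_log <- function(visits, path, origin = "2021-01-04") {
  origin_t <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  out <- data.frame(
    timestamp = format(origin_t + round(visits$time), "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC"),
    tag_id = visits$tag, feeder_id = visits$feeder, site_id = visits$site,
    access = visits$access, stringsAsFactors = FALSE)
  # the dialect forbids duplicate (timestamp, tag, feeder) triples; rounding
  # to second resolution can create them
  dup <- duplicated(paste(out$timestamp, out$tag_id, out$feeder_id))
  if (any(dup)) {
    message(sprintf("write_visit_log: dropping %d read(s) duplicated at second resolution",
                    sum(dup)))
    out <- out[!dup, ]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network as a weighted edge list CSV
#' @param net Weight matrix from [sri_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  idx <- which(upper.tri(net) & net > 0, arr.ind = TRUE)
  tg <- attr(net, "n_together")
  ei <- attr(net, "n_either")
  out <- data.frame(
    tag_a = rownames(net)[idx[, 1]], tag_b = colnames(net)[idx[, 2]],
    weight = net[idx],
    n_together = if (is.null(tg)) NA else tg[idx],
    n_either = if (is.null(ei)) NA else ei[idx],
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#' @inheritParams write_network_edgelist
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_adjacency_matrix(net, mode = "undirected",
                                           weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# write a CSV plus a JSON sidecar declaring its schema
write_csv_with_schema <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  schema <- list(columns = as.list(vapply(df, function(x) class(x)[1], "")))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate (optional) -> detect -> daily and site-period
#' networks -> density and network metrics -> assortment -> node
#' permutation tests -> patch discovery, writing tidy CSVs (each with a
#' JSON schema sidecar) and a manifest recording inputs, seeds, package
#' version and every exclusion applied. Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config A named list or path to a YAML file. Required: `seed`,
#'   `out_dir`. Either `simulate` (a list of [sim_config()] arguments, plus
#'   optional `n_control_sites`) or `visit_log` (path). Optional:
#'   `tau`, `k_max`, `detector` ("gmm"/"window"), `window`, `n_perm`,
#'   `min_records`, `run_discovery` (logical).
#' @return The output directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) {
    stop("run_pipeline: config must set an explicit seed", call. = FALSE)
  }
  if (is.null(config$out_dir)) {
    stop("run_pipeline: config must set out_dir", call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tau <- config$tau %||% 600
  k_max <- config$k_max %||% 10
  detector <- config$detector %||% "gmm"
  window <- config$window %||% 300
  n_perm <- config$n_perm %||% 1000
  min_records <- config$min_records %||% 100
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("flocknet")),
                   detector = detector, tau = tau, k_max = k_max,
                   n_perm = n_perm, min_records = min_records,
                   exclusions = list())

  stage <- "simulate/load"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      n_ctl <- sim_args$n_control_sites %||% 0
      sim_args$n_control_sites <- NULL
      sim_args$seed <- config$seed
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_colony(cfg, n_control_sites = n_ctl)
      visits <- sim$visits
      design <- sim$design
      write_csv_with_schema(sim$truth, file.path(out_dir, "events_truth.csv"))
      write_visit_log(visits, file.path(out_dir, "visits.csv"))
      manifest$input <- "simulated"
    } else {
      visits <- read_visit_log(config$visit_log)
      manifest$input <- config$visit_log
      manifest$rows_rejected <-
        unname(attr(visits, "counts")["rejected"])
      design <- load_design(config)
      sim <- NULL
    }

    stage <- "filter"
    filt <- filter_failed_days(visits, design)
    manifest$exclusions$failed_days <- nrow(filt$excluded)
    manifest$exclusions$failed_day_fraction <- filt$exclusion_fraction
    visits <- filt$visits

    stage <- "detect"
    events <- detect_flocks(visits, tau = tau, K_max = k_max,
                            method = detector, window = window)
    ev_out <- events[setdiff(names(events), "members")]
    write_csv_with_schema(ev_out, file.path(out_dir, "events.csv"))

    stage <- "networks"
    daily <- daily_networks(events)
    manifest$exclusions$daily_networks_dropped <-
      nrow(attr(daily, "dropped"))
    pnets <- period_networks(events, design)
    for (np in pnets) {
      write_network_edgelist(
        np$network,
        file.path(out_dir, sprintf("network_%s_%s.csv", np$site, np$period)))
    }

    stage <- "metrics"
    site_df <- site_density_series(visits, events, design)
    write_csv_with_schema(site_df, file.path(out_dir, "site_density.csv"))
    glob <- do.call(rbind, lapply(daily, function(d) {
      cbind(data.frame(site = d$site, feeder = d$feeder, day = d$day),
            global_metrics(d$network))
    }))
    if (!is.null(glob)) {
      glob$period <- design_period(design, glob$day)
      glob$exp_day <- design_day_index(design, glob$day)
      write_csv_with_schema(glob, file.path(out_dir, "daily_global_metrics.csv"))
    }
    indiv <- individual_density_series(visits, events, design,
                                       min_records = min_records)
    node_rows <- list()
    for (np in pnets) {
      nm <- node_metrics(np$network, np$gbi)
      nm$site <- np$site
      nm$period <- np$period
      node_rows[[length(node_rows) + 1L]] <- nm
    }
    nodes <- do.call(rbind, node_rows)
    treat_key <- paste(design$treatments$tag, design$treatments$site)
    tr <- stats::setNames(design$treatments$treatment, treat_key)
    nodes$treatment <- unname(tr[paste(nodes$tag, nodes$site)])
    keep_key <- paste(indiv$tag, indiv$site, indiv$period)
    nodes <- nodes[paste(nodes$tag, nodes$site, nodes$period) %in% keep_key, ]
    manifest$exclusions$individuals_kept <- length(unique(nodes$tag))
    write_csv_with_schema(indiv, file.path(out_dir, "individual_density.csv"))
    write_csv_with_schema(nodes, file.path(out_dir, "node_metrics.csv"))

    stage <- "assortment"
    assort_rows <- list()
    for (np in pnets) {
      labs <- tr[paste(rownames(np$network), np$site)]
      names(labs) <- rownames(np$network)
      if (length(unique(stats::na.omit(labs))) < 2) next
      a <- assortment_null(np$network, labs, n_perm = n_perm,
                           seed = config$seed)
      attr(a, "null") <- NULL
      a <- as.data.frame(a)
      a$site <- np$site
      a$period <- np$period
      assort_rows[[length(assort_rows) + 1L]] <- a
    }
    if (length(assort_rows)) {
      write_csv_with_schema(do.call(rbind, assort_rows),
                            file.path(out_dir, "assortment.csv"))
    }
    labels_all <- stats::setNames(tr[paste(design$treatments$tag,
                                           design$treatments$site)],
                                  design$treatments$tag)
    da <- suppressMessages(daily_assortment(daily, labels_all,
                                            n_perm = n_perm,
                                            seed = config$seed))
    manifest$exclusions$assortment_days_skipped <-
      nrow(attr(da, "skipped"))
    if (nrow(da)) {
      write_csv_with_schema(as.data.frame(da),
                            file.path(out_dir, "daily_assortment.csv"))
    }

    stage <- "permtest"
    perm_rows <- list()
    if (nrow(nodes) && length(unique(nodes$treatment)) > 1) {
      for (metric in c("weighted_degree", "average_association_strength",
                       "weighted_clustering", "weighted_eigenvector")) {
        pt <- suppressMessages(
          node_permutation_test(nodes, metric, n_perm = n_perm,
                                seed = config$seed))
        perm_rows[[metric]] <- data.frame(
          metric = metric, contrast = names(pt$observed),
          observed = unname(pt$observed), p = unname(pt$p),
          n_perm = pt$n_perm, stringsAsFactors = FALSE)
      }
      write_csv_with_schema(do.call(rbind, c(perm_rows,
                                             make.row.names = FALSE)),
                            file.path(out_dir, "node_permutation.csv"))
    }

    stage <- "discovery"
    if (isTRUE(config$run_discovery) && !is.null(sim)) {
      recs <- run_discovery_trials(sim, pnets)
      write_csv_with_schema(recs, file.path(out_dir, "discovery_records.csv"))
    }
    TRUE
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop(sprintf("run_pipeline: stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# design from config: feeder-role CSV, treatment CSV, period lengths
load_design <- function(config) {
  stopifnot(!is.null(config$feeders), !is.null(config$treatments),
            !is.null(config$days_pre), !is.null(config$days_exp))
  experiment_design(
    utils::read.csv(config$feeders, stringsAsFactors = FALSE),
    utils::read.csv(config$treatments, stringsAsFactors = FALSE),
    config$days_pre, config$days_exp)
}
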