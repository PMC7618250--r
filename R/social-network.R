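#' Simple-ratio-index association network from a GBI matrix
#'
#' For each pair of birds the simple ratio index (SRI) is the proportion of
#' flocking events containing either bird in which both occurred:
#' `w_ab = T / D`, with `T` the number of events containing both and `D`
#' the number containing `a` or `b`. It ranges from 0 (never in the same
#' flock) to 1 (always foraging together). Pairs never observed (`D = 0`)
#' get weight 0 and are marked unobserved.
#'
#' @param gbi Binary group-by-individual matrix (events x tags) from
#'   [events_to_gbi()].
#' @return Symmetric weight matrix with tag dimnames, zero diagonal, and
#'   attributes `n_together`, `n_either` (pair count matrices) and
#'   `observed` (logical, `D > 0`).
#' @export
#' @examples
#' g <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1))
#' colnames(g) <- c("a", "b")
#' sri_network(g)["a", "b"]  # 2 / 4
sri_network <- function(gbi) {
  if (is.null(dim(gbi)) || ncol(gbi) < 1) {
    stop("sri_network: GBI must have at least one column", call. = FALSE)
  }
  gbi <- as.matrix(gbi)
  storage.mode(gbi) <- "double"
  together <- crossprod(gbi)                    # T_ab (diag: events per bird)
  n_each <- diag(together)
  either <- outer(n_each, n_each, "+") - together  # |A or B|
  w <- ifelse(either > 0, together / either, 0)
  diag(w) <- 0
  diag(together) <- 0
  diag(either) <- 0
  observed <- either > 0
  diag(observed) <- FALSE
  structure(w, n_together = together, n_either = either, observed = observed)
}

#' Global metrics of an association network
#'
#' Network density (realised over possible dyads, unweighted), average
#' edge weight (mean of nonzero weights), and the global clustering
#' coefficient (3 x triangles / connected triples on the binarised graph).
#' Networks where fewer than `min_nodes` individuals are present are
#' flagged as filtered rather than raising an error, mirroring the
#' analysis rule that drops networks with fewer than three connected
#' individuals.
#'
#' @param net Weight matrix from [sri_network()].
#' @param min_nodes Minimum node count before the network is analysed.
#' @return One-row data.frame: `n_nodes`, `network_density`,
#'   `average_edge_weight`, `global_clustering`, `filtered`.
#' @export
global_metrics <- function(net, min_nodes = 3) {
  n <- nrow(net)
  if (n < min_nodes) {
    return(data.frame(n_nodes = n, network_density = NA_real_,
                      average_edge_weight = NA_real_,
                      global_clustering = NA_real_, filtered = TRUE))
  }
  up <- net[upper.tri(net)]
  nz <- up[up > 0]
  dens <- length(nz) / (n * (n - 1) / 2)
  aew <- if (length(nz)) mean(nz) else NA_real_
  g <- igraph::graph_from_adjacency_matrix(net > 0, mode = "undirected")
  gc <- igraph::transitivity(g, type = "global")
  if (is.nan(gc)) gc <- NA_real_
  data.frame(n_nodes = n, network_density = dens, average_edge_weight = aew,
             global_clustering = gc, filtered = FALSE)
}

# Barrat weighted local clustering:
# C_i = 1/(s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 * a_ij a_ih a_jh
barrat_clustering <- function(w) {
  a <- (w > 0) * 1
  s <- rowSums(w)
  k <- rowSums(a)
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) { out[i] <- 0; next }
    nb <- which(a[i, ] > 0)
    sub <- a[nb, nb, drop = FALSE]
    wi <- w[i, nb]
    out[i] <- sum(outer(wi, wi, "+") / 2 * sub) / (s[i] * (k[i] - 1))
  }
  stats::setNames(out, rownames(w))
}

# leading eigenvector by power iteration, per connected component,
# nonnegative, each component scaled to max 1; singletons get 0
power_eigenvector <- function(w, tol = 1e-10, max_iter = 10000) {
  n <- nrow(w)
  out <- stats::setNames(numeric(n), rownames(w))
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < 2) next
    m <- w[idx, idx, drop = FALSE]
    v <- rep(1 / sqrt(length(idx)), length(idx))
    for (it in seq_len(max_iter)) {
      v_new <- as.numeric(m %*% v)
      v_new <- abs(v_new)
      nrm <- sqrt(sum(v_new^2))
      if (nrm == 0) break
      v_new <- v_new / nrm
      if (max(abs(v_new - v)) < tol) { v <- v_new; break }
      v <- v_new
    }
    out[idx] <- v / max(v)
  }
  out
}

#' Per-individual network metrics
#'
#' Weighted degree (strength, sum of edge weights), average association
#' strength (strength / number of nonzero edges), Barrat weighted
#' clustering coefficient, weighted eigenvector centrality (power
#' iteration, tolerance 1e-10, computed per connected component and scaled
#' to maximum 1; isolated nodes get 0), and, when a GBI is supplied, the
#' mean flock size over the events each bird attended.
#'
#' @param net Weight matrix from [sri_network()].
#' @param gbi Optional GBI matrix for `mean_flock_size`.
#' @return data.frame keyed by `tag`.
#' @export
node_metrics <- function(net, gbi = NULL) {
  strength <- rowSums(net)
  degree <- rowSums(net > 0)
  aas <- ifelse(degree > 0, strength / degree, NA_real_)
  cl <- barrat_clustering(net)
  ev <- power_eigenvector(net)
  out <- data.frame(tag = rownames(net), weighted_degree = strength,
                    average_association_strength = aas,
                    weighted_clustering = cl, weighted_eigenvector = ev,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(gbi) && nrow(gbi)) {
    sizes <- rowSums(gbi)
    mfs <- vapply(out$tag, function(tg) {
      if (!tg %in% colnames(gbi)) return(NA_real_)
      sel <- gbi[, tg] == 1
      if (!any(sel)) NA_real_ else mean(sizes[sel])
    }, numeric(1))
    out$mean_flock_size <- unname(mfs)
  }
  out
}

#' Daily per-feeder association networks
#'
#' Builds one SRI network per (day, feeder) from that day's flocking
#' events. Networks in which fewer than `min_connected` individuals have at
#' least one association are dropped and logged, mirroring the day
#' exclusion used in the field analysis.
#'
#' @param events Event data.frame from [detect_flocks()] (must carry `day`).
#' @param min_connected Minimum number of connected individuals.
#' @return A list of entries (`day`, `feeder`, `site`, `network`, `gbi`),
#'   with a data.frame of dropped day-feeder combinations (and the reason)
#'   attached as attribute `"dropped"`.
#' @export
daily_networks <- function(events, min_connected = 3) {
  kept <- list()
  dropped <- list()
  if (nrow(events)) {
    key <- interaction(events$day, events$feeder, drop = TRUE)
    for (k in levels(key)) {
      ev <- events[key == k, , drop = FALSE]
      gbi <- events_to_gbi(ev)
      net <- sri_network(gbi)
      n_conn <- sum(rowSums(net > 0) > 0)
      site <- if ("site" %in% names(ev)) ev$site[1] else NA_character_
      if (n_conn < min_connected) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          day = ev$day[1], feeder = ev$feeder[1], site = site,
          n_connected = n_conn, reason = "fewer_than_min_connected",
          stringsAsFactors = FALSE)
      } else {
        kept[[length(kept) + 1L]] <- list(day = ev$day[1],
                                          feeder = ev$feeder[1],
                                          site = site, network = net,
                                          gbi = gbi)
      }
    }
  }
  drop_df <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(day = integer(), feeder = character(), site = character(),
               n_connected = integer(), reason = character(),
               stringsAsFactors = FALSE)
  structure(kept, dropped = drop_df)
}

#' Site-period association networks
#'
#' One network per (site, period) pooling all of that site's events in the
#' period, the scale at which individual network positions and assortment
#' are analysed.
#'
#' @param events Event data.frame from [detect_flocks()] with `site`.
#' @param design An [experiment_design()] giving the period boundary.
#' @return List of entries (`site`, `period`, `network`, `gbi`).
#' @export
period_networks <- function(events, design) {
  out <- list()
  if (!nrow(events)) return(out)
  events$period <- design_period(design, events$day)
  key <- interaction(events$site, events$period, drop = TRUE)
  for (k in levels(key)) {
    ev <- events[key == k, , drop = FALSE]
    gbi <- events_to_gbi(ev)
    out[[length(out) + 1L]] <- list(site = ev$site[1], period = ev$period[1],
                                    network = sri_network(gbi), gbi = gbi)
  }
  out
}
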