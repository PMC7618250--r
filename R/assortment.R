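#' Newman's weighted assortativity coefficient for a discrete node label
#'
#' Builds the mixing matrix `e_kl` — the fraction of total edge weight
#' joining label `k` to label `l`, counting both edge ends — and returns
#' `r = (sum_k e_kk - sum_k a_k^2) / (1 - sum_k a_k^2)` with marginals
#' `a_k = sum_l e_kl`. `r` is 1 when all edge weight lies within types,
#' 0 under random mixing, and -1 for a balanced all-between-type network.
#'
#' @param net Symmetric weight matrix with tag dimnames.
#' @param labels Named character vector (or factor) of node labels; every
#'   node in `net` must be labelled. Nodes with `NA` labels are dropped
#'   with a message.
#' @return The assortativity coefficient, or `NA` (with a warning) when all
#'   edge ends carry one single label so the coefficient is undefined.
#' @export
#' @examples
#' w <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
#' w["a", "b"] <- w["b", "a"] <- 1
#' w["c", "d"] <- w["d", "c"] <- 1
#' w["b", "c"] <- w["c", "b"] <- 1
#' assortativity_discrete(w, c(a = "low", b = "low", c = "high", d = "high"))
#' # 1/3
assortativity_discrete <- function(net, labels) {
  lab <- align_labels(net, labels)
  net <- lab$net
  labels <- lab$labels
  if (sum(net) == 0) {
    stop("assortativity_discrete: network has no nonzero edge", call. = FALSE)
  }
  types <- sort(unique(labels))
  L <- outer(labels, types, "==") * 1
  e <- t(L) %*% net %*% L
  e <- e / sum(e)
  a <- rowSums(e)
  denom <- 1 - sum(a^2)
  if (denom < .Machine$double.eps^0.5) {
    warning("assortativity undefined: all edge ends share one label")
    return(NA_real_)
  }
  (sum(diag(e)) - sum(a^2)) / denom
}

# drop NA-labelled nodes (with a message) and align label order to nodes
align_labels <- function(net, labels) {
  tags <- rownames(net)
  if (is.null(names(labels))) {
    stopifnot(length(labels) == nrow(net))
    names(labels) <- tags
  }
  labels <- as.character(labels[tags])
  missing <- is.na(labels)
  if (any(missing)) {
    message(sprintf("dropping %d node(s) with missing labels", sum(missing)))
    keep <- !missing
    net <- net[keep, keep, drop = FALSE]
    labels <- labels[keep]
  }
  list(net = net, labels = labels)
}

#' Edge-jackknife standard error of the assortativity coefficient
#'
#' Newman's jackknife: remove one nonzero edge at a time, recompute `r`,
#' and take `se = sqrt(sum_e (r_(-e) - r)^2)`.
#'
#' @inheritParams assortativity_discrete
#' @return The jackknife standard error; `NA` with a warning when fewer
#'   than two nonzero edges exist.
#' @export
jackknife_se <- function(net, labels) {
  lab <- align_labels(net, labels)
  net <- lab$net
  labels <- lab$labels
  idx <- which(upper.tri(net) & net > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) {
    warning("jackknife_se undefined with fewer than 2 edges")
    return(NA_real_)
  }
  r <- assortativity_discrete(net, labels)
  r_minus <- vapply(seq_len(nrow(idx)), function(e) {
    w2 <- net
    w2[idx[e, 1], idx[e, 2]] <- 0
    w2[idx[e, 2], idx[e, 1]] <- 0
    suppressWarnings(assortativity_discrete(w2, labels))
  }, numeric(1))
  sqrt(sum((r_minus - r)^2, na.rm = TRUE))
}

#' Assortativity with a node-label permutation null
#'
#' Shuffles the labels over the nodes `n_perm` times with the network held
#' fixed, yielding the null distribution of the coefficient under random
#' mixing. Reports the observed coefficient, its edge-jackknife SE, the
#' 2.5% / 97.5% null quantiles, and a two-tailed permutation p-value with
#' the +1 correction: `p = (1 + #{|r_null| >= |r_obs|}) / (n_perm + 1)`.
#'
#' @inheritParams assortativity_discrete
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return One-row data.frame of class `assortment_result`: `r`, `se`,
#'   `null_low`, `null_high`, `null_mean`, `p`, `n_perm`.
#' @export
assortment_null <- function(net, labels, n_perm = 1000, seed = 1) {
  lab <- align_labels(net, labels)
  net <- lab$net
  labels <- lab$labels
  if (length(unique(labels)) < 2) {
    stop("assortment_null: need at least two distinct labels", call. = FALSE)
  }
  if (n_perm < 100) {
    warning(sprintf("assortment_null: n_perm = %d is small; quantiles unstable",
                    n_perm))
  }
  r_obs <- assortativity_discrete(net, labels)
  se <- suppressWarnings(jackknife_se(net, labels))
  set.seed(seed)
  nulls <- vapply(seq_len(n_perm), function(b) {
    shuffled <- stats::setNames(sample(unname(labels)), names(labels))
    suppressWarnings(assortativity_discrete(net, shuffled))
  }, numeric(1))
  q <- stats::quantile(nulls, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  p <- (1 + sum(abs(nulls) >= abs(r_obs), na.rm = TRUE)) / (n_perm + 1)
  out <- data.frame(r = r_obs, se = se, null_low = q[1], null_high = q[2],
                    null_mean = mean(nulls, na.rm = TRUE), p = p,
                    n_perm = n_perm)
  class(out) <- c("assortment_result", class(out))
  attr(out, "null") <- nulls
  out
}

#' Daily assortativity with per-day exclusion rules
#'
#' Applies [assortment_null()] to each daily network, skipping (and
#' logging) days on which fewer than two individuals of each treatment are
#' present.
#'
#' @param daily List of daily networks from [daily_networks()].
#' @param labels Named treatment labels over all tags.
#' @param n_perm,seed Passed to [assortment_null()].
#' @return data.frame with one row per retained day-feeder (columns of
#'   [assortment_null()] plus `day`, `feeder`, `site`); skipped entries are
#'   attached as attribute `"skipped"`.
#' @export
daily_assortment <- function(daily, labels, n_perm = 1000, seed = 1) {
  rows <- list()
  skipped <- list()
  for (i in seq_along(daily)) {
    d <- daily[[i]]
    lab <- suppressMessages(align_labels(d$network, labels))
    counts <- table(lab$labels)
    if (length(counts) < 2 || any(counts < 2)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        day = d$day, feeder = d$feeder, site = d$site,
        reason = "fewer_than_two_per_treatment", stringsAsFactors = FALSE)
      next
    }
    res <- assortment_null(lab$net, lab$labels, n_perm = n_perm,
                           seed = seed + i)
    attr(res, "null") <- NULL
    res$day <- d$day
    res$feeder <- d$feeder
    res$site <- d$site
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r = numeric(), se = numeric(), null_low = numeric(),
               null_high = numeric(), null_mean = numeric(), p = numeric(),
               n_perm = integer(), day = integer(), feeder = character(),
               site = character(), stringsAsFactors = FALSE)
  skip_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(day = integer(), feeder = character(), site = character(),
               reason = character(), stringsAsFactors = FALSE)
  structure(out, skipped = skip_df)
}
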