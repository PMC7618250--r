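#' Split a time-ordered read stream into segments of feeding activity
#'
#' A segment is a maximal run of reads in which every gap between
#' consecutive reads is at most `tau` seconds. Segments are the unit the
#' mixture model is fitted to; the concatenation of all segments equals the
#' input.
#'
#' @param reads data.frame with at least `time` (seconds, nondecreasing)
#'   and `tag`; typically one feeder's stream.
#' @param tau Gap threshold in seconds (> 0). Default 600 s.
#' @return A list of segments, each a list with `times`, `tags`, and any
#'   `feeder` carried over from the input.
#' @export
#' @examples
#' r <- data.frame(time = c(0, 10, 20, 2000, 2010), tag = letters[1:5])
#' length(segment_reads(r, tau = 600))  # 2
segment_reads <- function(reads, tau = 600) {
  stopifnot(tau > 0)
  if (!nrow(reads)) return(list())
  if (is.unsorted(reads$time)) {
    stop("segment_reads: reads must be sorted by time (no silent sorting)",
         call. = FALSE)
  }
  gaps <- diff(reads$time)
  seg_id <- cumsum(c(1L, as.integer(gaps > tau)))
  feeder <- if ("feeder" %in% names(reads)) reads$feeder[1] else NA_character_
  lapply(split(seq_len(nrow(reads)), seg_id), function(idx) {
    list(feeder = feeder, times = reads$time[idx], tags = reads$tag[idx])
  })
}

# log-sum-exp by row
.row_lse <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# one EM fit of a K-component univariate Gaussian mixture; deterministic
# quantile initialisation on the (sorted) times, variance floor 1 s^2
.em_gauss <- function(x, K, var_floor = 1, max_iter = 500, tol = 1e-6) {
  n <- length(x)
  mu <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE,
                        type = 7)
  sp <- max(diff(range(x)) / K, 1)^2
  v <- rep(max(sp, var_floor), K)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dev <- outer(x, mu, "-")^2
    logd <- sweep(-sweep(dev, 2, 2 * v, "/"), 2,
                  log(pi_k) - 0.5 * log(2 * pi * v), "+")
    lse <- .row_lse(logd)
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    pi_k <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, var = v, weight = pi_k, loglik = ll, resp = resp,
       bic = -2 * ll + (3 * K - 1) * log(n))
}

# force label runs to be contiguous in time: while some label occupies
# multiple runs, merge the shortest such run into its larger neighbour
.make_contiguous <- function(labels) {
  repeat {
    r <- rle(labels)
    dup <- r$values[duplicated(r$values)]
    if (!length(dup)) return(labels)
    cand <- which(r$values %in% unique(dup))
    j <- cand[which.min(r$lengths[cand])]
    left <- if (j > 1) r$lengths[j - 1] else -1L
    right <- if (j < length(r$values)) r$lengths[j + 1] else -1L
    new_lab <- if (left >= right) r$values[j - 1] else r$values[j + 1]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    labels[starts[j]:ends[j]] <- new_lab
  }
}

#' Cluster reads in one segment into flocking events with a Gaussian mixture
#'
#' Fits univariate Gaussian mixtures with K = 1..`K_max` components to the
#' read times by expectation-maximisation (deterministic quantile seeding,
#' variance floor 1 s^2, at most 500 iterations, log-likelihood tolerance
#' 1e-6), selects K by minimum BIC, labels each read by maximum posterior
#' responsibility (ties broken toward the earlier-mean component), and
#' enforces temporal contiguity by majority relabelling of label runs
#' interleaved inside another label's span. Returned label blocks are
#' contiguous in time and numbered 1..K' in time order.
#'
#' @param segment A segment from [segment_reads()] (list with `times`), or
#'   a numeric vector of read times.
#' @param K_max Maximum number of mixture components to consider (>= 1).
#' @return Integer vector of per-read event labels.
#' @export
fit_event_mixture <- function(segment, K_max = 10) {
  if (K_max < 1) stop("fit_event_mixture: K_max must be >= 1", call. = FALSE)
  x <- if (is.list(segment)) segment$times else as.numeric(segment)
  n <- length(x)
  if (n == 0) return(integer())
  if (n == 1) return(1L)

  # BIC search over K with early stopping once the criterion has worsened
  # on two consecutive candidate sizes
  best <- NULL
  worse <- 0L
  for (K in seq_len(min(K_max, n))) {
    fit <- .em_gauss(x, K)
    if (is.null(best) || fit$bic < best$bic) {
      best <- fit
      worse <- 0L
    } else {
      worse <- worse + 1L
      if (worse >= 2L) break
    }
  }
  K <- length(best$mu)
  if (K == 1) return(rep(1L, n))

  # argmax responsibility; ties go to the component with the earlier mean
  ord <- order(best$mu)
  resp <- best$resp[, ord, drop = FALSE]
  labels <- max.col(resp, ties.method = "first")
  labels <- .make_contiguous(labels)
  # renumber in time order
  as.integer(factor(labels, levels = unique(labels)))
}

#' Convert contiguous event labels to non-overlapping flocking events
#'
#' @param segment A segment from [segment_reads()].
#' @param labels Integer labels as returned by [fit_event_mixture()]; must
#'   form contiguous blocks in time.
#' @return data.frame with one row per event: `feeder`, `start`, `end`,
#'   `n_members`, `n_reads`, `day`, and `members` (list column of tag
#'   character vectors).
#' @export
labels_to_events <- function(segment, labels) {
  stopifnot(length(labels) == length(segment$times))
  if (!length(labels)) return(empty_events())
  r <- rle(labels)
  if (anyDuplicated(r$values)) {
    stop("labels_to_events: labels are not contiguous in time", call. = FALSE)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- lapply(seq_along(starts), function(b) {
    idx <- starts[b]:ends[b]
    tms <- segment$times[idx]
    mem <- sort(unique(segment$tags[idx]))
    data.frame(feeder = segment$feeder, start = min(tms), end = max(tms),
               n_members = length(mem), n_reads = length(idx),
               day = floor(min(tms) / 86400) + 1L,
               members = I(list(mem)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(feeder = character(), start = numeric(), end = numeric(),
             n_members = integer(), n_reads = integer(), day = integer(),
             members = I(list()), stringsAsFactors = FALSE)
}

#' Build the group-by-individual (GBI) matrix from flocking events
#'
#' Rows are events in chronological order; columns are the sorted union of
#' tags; entry 1 marks membership. The total of all entries equals the sum
#' of event member counts (conservation).
#'
#' @param events Event data.frame from [labels_to_events()] or
#'   [detect_flocks()].
#' @return Binary matrix with event rownames and tag colnames; the event
#'   metadata (without the membership list) is attached as attribute
#'   `"events"`.
#' @export
events_to_gbi <- function(events) {
  if (!nrow(events)) {
    m <- matrix(0L, 0, 0)
    attr(m, "events") <- events
    return(m)
  }
  events <- events[order(events$start), , drop = FALSE]
  tags <- sort(unique(unlist(events$members)))
  m <- matrix(0L, nrow(events), length(tags),
              dimnames = list(sprintf("e%d", seq_len(nrow(events))), tags))
  for (i in seq_len(nrow(events))) {
    m[i, events$members[[i]]] <- 1L
  }
  meta <- events[setdiff(names(events), "members")]
  rownames(meta) <- rownames(m)
  attr(m, "events") <- meta
  m
}

#' Detect flocking events across a visit log
#'
#' Per feeder: segment the read stream with gap threshold `tau`, then
#' cluster each segment's reads into events, either with the Gaussian
#' mixture model (`method = "gmm"`) or with a fixed tumbling-window
#' fallback (`method = "window"`, windows of `window` seconds aligned to
#' the segment start).
#'
#' @param visits Visit data.frame (`time`, `tag`, `feeder`; optionally
#'   `site`, `day`).
#' @param tau Segmentation gap threshold in seconds.
#' @param K_max Maximum mixture components per segment (gmm method).
#' @param method `"gmm"` or `"window"`.
#' @param window Tumbling-window length in seconds (window method).
#' @return Event data.frame as in [labels_to_events()], with a `site`
#'   column when present in the input.
#' @export
detect_flocks <- function(visits, tau = 600, K_max = 10,
                          method = c("gmm", "window"), window = 300) {
  method <- match.arg(method)
  if (!nrow(visits)) return(empty_events())
  out <- list()
  for (fid in unique(visits$feeder)) {
    v <- visits[visits$feeder == fid, , drop = FALSE]
    v <- v[order(v$time), , drop = FALSE]
    site <- if ("site" %in% names(v)) v$site[1] else NA_character_
    segs <- segment_reads(v, tau = tau)
    for (seg in segs) {
      labels <- if (method == "gmm") {
        fit_event_mixture(seg, K_max = K_max)
      } else {
        bin <- floor((seg$times - seg$times[1]) / window)
        as.integer(factor(bin, levels = unique(bin)))
      }
      ev <- labels_to_events(seg, labels)
      if (nrow(ev)) {
        ev$site <- site
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (!length(out)) return(empty_events())
  res <- do.call(rbind, out)
  res <- res[order(res$feeder, res$start), ]
  rownames(res) <- NULL
  res
}
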