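#' Define a patch-discovery trial
#'
#' A novel feeder (one near each selective feeder) is deployed before
#' sunrise and left in place for one day; the trial start is the first
#' second of the trial day's recording window.
#'
#' @param site Site identifier.
#' @param period `"pre"` or `"during"`.
#' @param day Study day index of the trial.
#' @param novel_feeders Character vector of novel feeder identifiers.
#' @param start Trial start in seconds from study start.
#' @return List of class `discovery_trial`.
#' @export
discovery_trial <- function(site, period, day, novel_feeders, start) {
  stopifnot(length(novel_feeders) >= 1, period %in% c("pre", "during"))
  structure(list(site = site, period = period, day = as.integer(day),
                 novel_feeders = novel_feeders, start = start),
            class = "discovery_trial")
}

#' Select the birds eligible for a patch-discovery trial
#'
#' Eligible birds are those recorded at the site's selective (established)
#' feeders on the trial day and recorded at least `min_records` times at
#' that site across the density-manipulation period. Birds seen only at
#' the novel feeders that day are not eligible.
#'
#' @param visits Full visit data.frame (selective feeders only).
#' @param trial A [discovery_trial()].
#' @param design An [experiment_design()].
#' @param min_records Manipulation-period read threshold (default 100).
#' @return Character vector of eligible tags.
#' @export
select_trial_birds <- function(visits, trial, design, min_records = 100) {
  v <- visits[visits$site == trial$site, , drop = FALSE]
  on_day <- unique(v$tag[v$day == trial$day])
  per <- design_period(design, v$day)
  manip_counts <- table(v$tag[per == "during"])
  enough <- names(manip_counts)[manip_counts >= min_records]
  sort(intersect(on_day, enough))
}

#' Score a patch-discovery trial
#'
#' A bird discovered iff it has at least one read at any of the trial's
#' novel feeders; its latency is the time from trial start to its first
#' arrival (the earliest read across both novel feeders), and arrival
#' orders are assigned by [order_with_ties()].
#'
#' @param novel_reads data.frame of reads at the novel feeders (`time`,
#'   `tag`, `feeder`).
#' @param trial A [discovery_trial()].
#' @param eligible Character vector from [select_trial_birds()].
#' @param tie_window Tie window in seconds passed to [order_with_ties()].
#' @return data.frame with one row per eligible bird: `tag`, `site`,
#'   `period`, `discovered`, `first_arrival`, `latency`, `order`.
#' @export
score_discovery <- function(novel_reads, trial, eligible, tie_window = 600) {
  nr <- novel_reads[novel_reads$feeder %in% trial$novel_feeders, ,
                    drop = FALSE]
  if (nrow(nr) && any(nr$time < trial$start)) {
    stop("score_discovery: reads before trial start (clock misconfiguration)",
         call. = FALSE)
  }
  first <- if (nrow(nr)) {
    tapply(nr$time, nr$tag, min)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  first <- first[names(first) %in% eligible]

  out <- data.frame(tag = eligible, site = trial$site, period = trial$period,
                    discovered = eligible %in% names(first),
                    first_arrival = NA_real_, latency = NA_real_,
                    order = NA_integer_, stringsAsFactors = FALSE)
  if (length(first)) {
    ord <- order(first)
    arrived <- names(first)[ord]
    times <- as.numeric(first)[ord]
    ranks <- order_with_ties(times - trial$start, tie_window = tie_window)
    m <- match(arrived, out$tag)
    out$first_arrival[m] <- times
    out$latency[m] <- times - trial$start
    out$order[m] <- ranks
  }
  out
}

#' Tie-grouped arrival order
#'
#' Greedy grouping anchored at each group's first arrival: a bird joins the
#' current group iff its arrival minus the group anchor is at most
#' `tie_window` seconds (default 10 minutes, so birds visiting within
#' 10 min of each other count as discovering at the same time); otherwise
#' it starts the next group. All members of group g receive order g.
#'
#' @param times Sorted ascending arrival times (seconds).
#' @param tie_window Window in seconds (default 600).
#' @return Integer ranks, same length as `times`.
#' @export
#' @examples
#' order_with_ties(c(0, 300, 900))  # 1 1 2
order_with_ties <- function(times, tie_window = 600) {
  if (!length(times)) return(integer())
  if (is.unsorted(times)) {
    stop("order_with_ties: times must be sorted ascending", call. = FALSE)
  }
  ranks <- integer(length(times))
  g <- 1L
  anchor <- times[1]
  for (i in seq_along(times)) {
    if (times[i] - anchor > tie_window) {
      g <- g + 1L
      anchor <- times[i]
    }
    ranks[i] <- g
  }
  ranks
}

#' Simulate and score patch-discovery trials for a whole colony
#'
#' For each site and period, runs one trial: arrivals are generated by
#' [simulate_discovery_trial()] over that site-period's association
#' network, then scored against the eligibility rules. The trial day is
#' the last day of the period; the trial spans the daily recording window.
#'
#' @param sim A [simulate_colony()] result.
#' @param networks Site-period networks from [period_networks()].
#' @param tie_window Tie window (s) for arrival order.
#' @return DiscoveryRecord data.frame across all trials, with `treatment`
#'   attached.
#' @export
run_discovery_trials <- function(sim, networks, tie_window = 600) {
  design <- sim$design
  cfg <- sim$config
  trial_len <- cfg$day_end - cfg$day_start
  treat_key <- paste(design$treatments$tag, design$treatments$site)
  treatment <- stats::setNames(design$treatments$treatment, treat_key)

  rows <- list()
  for (np in networks) {
    day <- if (np$period == "pre") design$days_pre else
      design$days_pre + design$days_exp
    start <- (day - 1) * 86400 + cfg$day_start
    trial <- discovery_trial(np$site, np$period, day,
                             novel_feeders = paste0(np$site, "_N", 1:2),
                             start = start)
    eligible <- select_trial_birds(
      sim$visits, trial, design,
      min_records = cfg$eligibility_min_reads)
    if (!length(eligible)) next
    arrivals <- simulate_discovery_trial(
      np$network, cfg, trial_len,
      seed = derive_seed(cfg$seed, 606L, day, nchar(np$site)))
    arr <- arrivals[!is.na(arrivals)]
    novel_reads <- if (length(arr)) {
      data.frame(time = start + as.numeric(arr), tag = names(arr),
                 feeder = trial$novel_feeders[1], stringsAsFactors = FALSE)
    } else {
      data.frame(time = numeric(), tag = character(), feeder = character(),
                 stringsAsFactors = FALSE)
    }
    rec <- score_discovery(novel_reads, trial, eligible,
                           tie_window = tie_window)
    rec$treatment <- unname(treatment[paste(rec$tag, rec$site)])
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows)) {
    return(data.frame(tag = character(), site = character(),
                      period = character(), discovered = logical(),
                      first_arrival = numeric(), latency = numeric(),
                      order = integer(), treatment = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
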