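#' Assign feeder roles from pre-period visitation
#'
#' At a uniformly random half of the experimental sites the feeder holding
#' the majority of pre-period visits becomes the high-density feeder; at
#' the other half it becomes the low-density feeder. Control sites keep
#' both feeders as `control`. Tied counts are broken by feeder identifier
#' order and logged.
#'
#' @param pre_counts data.frame with `site`, `feeder`, `reads` (pre-period
#'   read counts); two feeders per site.
#' @param experimental_sites Character vector of sites to manipulate; all
#'   other sites in `pre_counts` become controls.
#' @param seed Integer seed for the random halving.
#' @return data.frame `site`, `feeder`, `role`.
#' @export
assign_feeder_roles <- function(pre_counts, experimental_sites, seed) {
  stopifnot(all(c("site", "feeder", "reads") %in% names(pre_counts)))
  for (s in experimental_sites) {
    if (sum(pre_counts$site == s) != 2) {
      stop(sprintf("assign_feeder_roles: site '%s' must have two feeders", s),
           call. = FALSE)
    }
  }
  set.seed(seed)
  experimental_sites <- sort(experimental_sites)
  n <- length(experimental_sites)
  majority_high <- if (n > 0) {
    sample(experimental_sites, floor(n / 2))
  } else character()

  out <- pre_counts[c("site", "feeder")]
  out$role <- "control"
  for (s in experimental_sites) {
    rows <- which(pre_counts$site == s)
    rows <- rows[order(pre_counts$feeder[rows])]
    cnt <- pre_counts$reads[rows]
    if (cnt[1] == cnt[2]) {
      message(sprintf("assign_feeder_roles: tie at site '%s'; broken by feeder id order", s))
    }
    maj <- rows[which.max(cnt)]  # ties -> first in feeder id order
    min_ <- setdiff(rows, maj)
    if (s %in% majority_high) {
      out$role[maj] <- "high"; out$role[min_] <- "low"
    } else {
      out$role[maj] <- "low"; out$role[min_] <- "high"
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign birds to density treatments from pre-period read counts
#'
#' At each site, birds recorded at least `min_records` times in the
#' pre-experimental period are eligible; `round(low_fraction * n_eligible)`
#' of them (at least one) are sampled without replacement into the
#' low-density treatment. Every other PIT-tagged bird at the site —
#' the remaining eligible birds and all non-eligible ones — retains access
#' at the high-density feeder.
#'
#' @param pre_visits data.frame with `tag`, `site`, `reads` (pre-period
#'   counts per bird at that site).
#' @param min_records Eligibility threshold (default 100 reads).
#' @param low_fraction Fraction of eligible birds assigned low (default 0.2).
#' @param seed Integer seed.
#' @return data.frame `tag`, `site`, `treatment` (`"low"` / `"high"`).
#' @export
assign_bird_treatments <- function(pre_visits, min_records = 100,
                                   low_fraction = 0.20, seed) {
  stopifnot(all(c("tag", "site", "reads") %in% names(pre_visits)))
  set.seed(seed)
  out <- pre_visits[order(pre_visits$site, pre_visits$tag),
                    c("tag", "site")]
  reads <- pre_visits$reads[order(pre_visits$site, pre_visits$tag)]
  out$treatment <- "high"
  for (s in unique(out$site)) {
    rows <- which(out$site == s)
    eligible <- rows[reads[rows] >= min_records]
    if (!length(eligible)) {
      stop(sprintf("assign_bird_treatments: no eligible bird at site '%s'", s),
           call. = FALSE)
    }
    n_low <- max(1L, round(low_fraction * length(eligible)))
    low <- if (length(eligible) == 1) eligible else sample(eligible, n_low)
    out$treatment[low] <- "low"
  }
  rownames(out) <- NULL
  out
}

#' Exclude site-days on which a feeder was not recording
#'
#' A site-day is dropped when exactly one of the site's two feeders has
#' zero reads while its partner recorded, or when neither recorded
#' (no-data day). The exclusion fraction is reported over all site-days of
#' the study period.
#'
#' @param visits Visit data.frame (`site`, `feeder`, `day`, ...).
#' @param design An [experiment_design()].
#' @return List: `visits` (filtered), `excluded` (data.frame `site`, `day`,
#'   `reason`), `exclusion_fraction`.
#' @export
filter_failed_days <- function(visits, design) {
  total_days <- design$days_pre + design$days_exp
  sites <- unique(design$feeders$site)
  excluded <- list()
  keep <- rep(TRUE, nrow(visits))
  for (s in sites) {
    fds <- design$feeders$feeder[design$feeders$site == s]
    for (d in seq_len(total_days)) {
      sel <- visits$site == s & visits$day == d
      n_by_feeder <- vapply(fds, function(f) sum(visits$feeder[sel] == f),
                            numeric(1))
      n_silent <- sum(n_by_feeder == 0)
      if (n_silent == 0) next
      reason <- if (n_silent == length(fds)) "no_data" else "one_feeder_silent"
      excluded[[length(excluded) + 1L]] <- data.frame(
        site = s, day = d, reason = reason, stringsAsFactors = FALSE)
      keep[sel] <- FALSE
    }
  }
  excl <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(site = character(), day = integer(), reason = character(),
               stringsAsFactors = FALSE)
  list(visits = visits[keep, , drop = FALSE], excluded = excl,
       exclusion_fraction = nrow(excl) / (length(sites) * total_days))
}

#' Daily site-level density measures
#'
#' Per feeder-day: the proportion of the site's recordings captured at that
#' feeder, the number of distinct individuals recorded, and the mean flock
#' size of that day's detected events. "Recordings" are raw antenna reads,
#' including access-denied visits.
#'
#' @param visits Filtered visit data.frame (see [filter_failed_days()]).
#' @param events Event data.frame from [detect_flocks()].
#' @param design An [experiment_design()].
#' @return data.frame: `site`, `feeder`, `role`, `day`, `period`,
#'   `exp_day`, `n_reads`, `prop_recordings`, `n_individuals`,
#'   `mean_flock_size`.
#' @export
site_density_series <- function(visits, events, design) {
  if (!nrow(visits)) {
    return(data.frame(site = character(), feeder = character(),
                      role = character(), day = integer(),
                      period = character(), exp_day = integer(),
                      n_reads = integer(), prop_recordings = numeric(),
                      n_individuals = integer(), mean_flock_size = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_reads = visits$time),
                          by = list(site = visits$site,
                                    feeder = visits$feeder,
                                    day = visits$day),
                          FUN = length)
  inds <- stats::aggregate(list(n_individuals = visits$tag),
                           by = list(site = visits$site,
                                     feeder = visits$feeder,
                                     day = visits$day),
                           FUN = function(x) length(unique(x)))
  agg <- merge(agg, inds, by = c("site", "feeder", "day"))

  site_tot <- stats::aggregate(list(site_reads = agg$n_reads),
                               by = list(site = agg$site, day = agg$day),
                               FUN = sum)
  agg <- merge(agg, site_tot, by = c("site", "day"))
  stopifnot(all(agg$site_reads > 0))
  agg$prop_recordings <- agg$n_reads / agg$site_reads
  agg$site_reads <- NULL

  if (nrow(events)) {
    mfs <- stats::aggregate(list(mean_flock_size = events$n_members),
                            by = list(feeder = events$feeder,
                                      day = events$day),
                            FUN = mean)
    agg <- merge(agg, mfs, by = c("feeder", "day"), all.x = TRUE)
  } else {
    agg$mean_flock_size <- NA_real_
  }
  agg <- merge(agg, design$feeders, by = c("site", "feeder"))
  agg$period <- design_period(design, agg$day)
  agg$exp_day <- design_day_index(design, agg$day)
  agg <- agg[order(agg$site, agg$day, agg$feeder),
             c("site", "feeder", "role", "day", "period", "exp_day",
               "n_reads", "prop_recordings", "n_individuals",
               "mean_flock_size")]
  rownames(agg) <- NULL
  agg
}

#' Individual-level density measures per site and period
#'
#' Keeps only birds recorded at least `min_records` times in *both*
#' periods at the site. For each kept bird-period: the proportion of
#' access-granted reads made at the feeder the bird was assigned to (low
#' birds at the low-density feeder, all others at the high-density feeder),
#' and the mean size of the flocks the bird attended. Birds recorded at
#' several sites are scored per site independently.
#'
#' @param visits Visit data.frame.
#' @param events Event data.frame from [detect_flocks()].
#' @param design An [experiment_design()].
#' @param min_records Per-period inclusion threshold (default 100).
#' @return data.frame: `tag`, `site`, `period`, `treatment`, `n_reads`,
#'   `prop_assigned`, `mean_flock_size`.
#' @export
individual_density_series <- function(visits, events, design,
                                      min_records = 100) {
  empty <- data.frame(tag = character(), site = character(),
                      period = character(), treatment = character(),
                      n_reads = integer(), prop_assigned = numeric(),
                      mean_flock_size = numeric(), stringsAsFactors = FALSE)
  if (!nrow(visits)) return(empty)
  visits$period <- design_period(design, visits$day)
  cnt <- stats::aggregate(list(n_reads = visits$time),
                          by = list(tag = visits$tag, site = visits$site,
                                    period = visits$period),
                          FUN = length)
  wide <- stats::reshape(cnt, idvar = c("tag", "site"), timevar = "period",
                         direction = "wide")
  for (col in c("n_reads.pre", "n_reads.during")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
  }
  ok <- !is.na(wide$n_reads.pre) & !is.na(wide$n_reads.during) &
    wide$n_reads.pre >= min_records & wide$n_reads.during >= min_records
  keep <- wide[ok, c("tag", "site")]
  if (!nrow(keep)) return(empty)

  treat_key <- paste(design$treatments$tag, design$treatments$site)
  treatment <- stats::setNames(design$treatments$treatment, treat_key)

  if (nrow(events)) {
    events$period <- design_period(design, events$day)
  }

  rows <- list()
  for (i in seq_len(nrow(keep))) {
    tg <- keep$tag[i]; s <- keep$site[i]
    tr <- unname(treatment[paste(tg, s)])
    if (is.na(tr)) tr <- "unassigned"
    assigned_role <- if (tr == "low") "low" else "high"
    assigned_feeder <- feeder_of_role(design, s, assigned_role)
    for (per in c("pre", "during")) {
      v <- visits[visits$tag == tg & visits$site == s &
                    visits$period == per, , drop = FALSE]
      granted <- v[v$access == 1, , drop = FALSE]
      prop <- if (is.na(assigned_feeder) || !nrow(granted)) NA_real_ else
        sum(granted$feeder == assigned_feeder) / nrow(granted)
      mfs <- NA_real_
      if (nrow(events)) {
        ev <- events[events$site == s & events$period == per, , drop = FALSE]
        if (nrow(ev)) {
          has <- vapply(ev$members, function(m) tg %in% m, logical(1))
          if (any(has)) mfs <- mean(ev$n_members[has])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tag = tg, site = s, period = per, treatment = tr,
        n_reads = nrow(v), prop_assigned = prop, mean_flock_size = mfs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
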