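#' Simulate feeder visit streams for a colony
#'
#' Generates time-stamped antenna reads at two feeders per site. Flocking
#' events arrive at each feeder as a Poisson process within the daily
#' recording window; each event is seeded with one bird and recruits others
#' with probability increasing (logistically) in the pairwise preference
#' weight, scaled so that the expected flock size is about
#' `flock_size_mean` when the whole site population is available. Each
#' member emits `1 + Poisson(reads_per_member)` reads normally jittered
#' around the event centre. During the experimental period a low-assigned
#' bird chooses its assigned feeder with probability `compliance` and the
#' high-density feeder otherwise (recorded there but denied access);
#' high-assigned birds occasionally stray to the low-density feeder where
#' they are likewise recorded but denied.
#'
#' Random streams are split per (site, day, feeder) from the master seed,
#' so any subset of days regenerates identically in isolation.
#'
#' @param pop A [simulate_population()] result.
#' @param config A [sim_config()].
#' @param design An [experiment_design()] covering the same sites.
#' @param period Which days to generate: `"both"`, `"pre"` or `"during"`.
#' @return A list with `visits` (data.frame: `time` in seconds from study
#'   start, `tag`, `feeder`, `site`, `access` 0/1, `day`, `period`) sorted
#'   by feeder then time, and `truth` — the planted flocking events
#'   (`site`, `feeder`, `day`, `period`, `center`, `start`, `end`,
#'   `n_members`, `n_reads`, `members` semicolon-joined) for detector
#'   benchmarking.
#' @export
simulate_visits <- function(pop, config, design,
                            period = c("both", "pre", "during")) {
  stopifnot(inherits(pop, "colony_population"),
            inherits(config, "sim_config"),
            inherits(design, "experiment_design"))
  period <- match.arg(period)

  sites <- unique(pop$birds$site)
  if (!setequal(sites, unique(design$feeders$site))) {
    stop("simulate_visits: design sites do not match population sites",
         call. = FALSE)
  }
  days <- switch(period,
    pre    = seq_len(design$days_pre),
    during = design$days_pre + seq_len(design$days_exp),
    both   = seq_len(design$days_pre + design$days_exp)
  )

  treat <- stats::setNames(design$treatments$treatment, design$treatments$tag)
  mu <- config$flock_size_mean
  sigma <- config$read_jitter
  hours <- (config$day_end - config$day_start) / 3600

  visit_chunks <- list()
  truth_chunks <- list()

  total_days <- design$days_pre + design$days_exp
  for (si in seq_along(sites)) {
    s <- sites[si]
    site_tags <- pop$birds$tag[pop$birds$site == s]
    w_site <- pop$preference[site_tags, site_tags, drop = FALSE]
    feeders <- design$feeders[design$feeders$site == s, ]
    feeders <- feeders[order(feeders$feeder), ]
    is_control <- all(feeders$role == "control")

    # one-feeder outages, drawn day-indexed from a per-site stream so any
    # subset of days regenerates identically
    silent_by_day <- rep(0L, total_days)
    if (config$failure_rate > 0) {
      set.seed(derive_seed(config$seed, si, 998L))
      failed <- stats::runif(total_days) < config$failure_rate
      silent_by_day[failed] <- sample(1:2, sum(failed), replace = TRUE)
    }

    for (d in days) {
      per <- design_period(design, d)
      silent <- silent_by_day[d]
      for (fi in 1:2) {
        if (fi == silent) next
        fid <- feeders$feeder[fi]
        role <- feeders$role[fi]
        set.seed(derive_seed(config$seed, si, d, fi))
        n_ev <- stats::rpois(1, config$flock_rate * hours)
        if (n_ev == 0) next
        centers <- sort(stats::runif(n_ev, config$day_start, config$day_end)) +
          (d - 1) * 86400
        win_lo <- (d - 1) * 86400 + config$day_start
        win_hi <- (d - 1) * 86400 + config$day_end

        for (ev in seq_len(n_ev)) {
          # which birds would be at this feeder right now
          u <- stats::runif(length(site_tags))
          if (per == "pre" || is_control) {
            at_this <- (u < 0.5) == (fi == 1L)
          } else {
            tr <- treat[site_tags]
            choice_low <- ifelse(tr == "low",
                                 u < config$compliance,
                                 u < config$stray_prob)
            at_this <- if (role == "low") choice_low else !choice_low
          }
          avail <- which(at_this)
          if (!length(avail)) next

          seed_i <- if (length(avail) == 1) avail else sample(avail, 1)
          pref <- stats::plogis(config$preference_scale * w_site[seed_i, ])
          kappa <- (mu - 1) / sum(pref[-seed_i])
          members <- seed_i
          others <- setdiff(avail, seed_i)
          if (length(others)) {
            p_rec <- pmin(1, kappa * pref[others])
            members <- c(seed_i,
                         others[stats::runif(length(others)) < p_rec])
          }

          n_reads_m <- 1L + stats::rpois(length(members),
                                         config$reads_per_member)
          tags_ev <- rep(site_tags[members], n_reads_m)
          t_ev <- stats::rnorm(length(tags_ev), centers[ev], sigma)
          t_ev <- pmin(pmax(t_ev, centers[ev] - 3 * sigma), centers[ev] + 3 * sigma)
          t_ev <- pmin(pmax(t_ev, win_lo), win_hi)

          if (per == "pre" || is_control) {
            acc <- rep(1L, length(tags_ev))
          } else {
            tr_ev <- treat[tags_ev]
            acc <- as.integer(
              (role == "low" & tr_ev == "low") |
              (role == "high" & tr_ev != "low")
            )
          }
          visit_chunks[[length(visit_chunks) + 1L]] <- data.frame(
            time = t_ev, tag = tags_ev, feeder = fid, site = s,
            access = acc, day = d, period = per, stringsAsFactors = FALSE
          )
          truth_chunks[[length(truth_chunks) + 1L]] <- data.frame(
            site = s, feeder = fid, day = d, period = per,
            center = centers[ev], start = min(t_ev), end = max(t_ev),
            n_members = length(members), n_reads = length(tags_ev),
            members = paste(sort(site_tags[members]), collapse = ";"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }

  empty_visits <- data.frame(time = numeric(), tag = character(),
                             feeder = character(), site = character(),
                             access = integer(), day = integer(),
                             period = character(), stringsAsFactors = FALSE)
  empty_truth <- data.frame(site = character(), feeder = character(),
                            day = integer(), period = character(),
                            center = numeric(), start = numeric(),
                            end = numeric(), n_members = integer(),
                            n_reads = integer(), members = character(),
                            stringsAsFactors = FALSE)
  visits <- if (length(visit_chunks)) {
    do.call(rbind, visit_chunks)
  } else empty_visits
  truth <- if (length(truth_chunks)) {
    do.call(rbind, truth_chunks)
  } else empty_truth
  if (nrow(visits)) {
    visits <- visits[order(visits$feeder, visits$time), ]
    rownames(visits) <- NULL
    truth <- truth[order(truth$feeder, truth$center), ]
    rownames(truth) <- NULL
  }
  list(visits = visits, truth = truth)
}

#' Run the whole colony simulation, including design assignment
#'
#' Simulates the pre-experimental period with free access at both feeders,
#' assigns feeder roles and bird treatments from the pre-period read counts
#' (exactly the rules of [assign_feeder_roles()] and
#' [assign_bird_treatments()]), then simulates the experimental period
#' under those restrictions.
#'
#' @param config A [sim_config()].
#' @param n_control_sites Number of sites (chosen at random from the
#'   configured sites) left unmanipulated as controls.
#' @return A list of class `colony_sim`: `visits`, `truth`, `design`,
#'   `population`, `config`.
#' @export
#' @examples
#' sim <- simulate_colony(sim_config(n_sites = 1, birds_per_site = 10,
#'                                   days_pre = 2, days_exp = 2,
#'                                   eligibility_min_reads = 5, seed = 1))
#' head(sim$visits)
simulate_colony <- function(config, n_control_sites = 0) {
  stopifnot(inherits(config, "sim_config"),
            n_control_sites < config$n_sites)
  pop <- simulate_population(config)
  sites <- unique(pop$birds$site)

  set.seed(derive_seed(config$seed, 202L))
  control_sites <- if (n_control_sites > 0) {
    sort(sample(sites, n_control_sites))
  } else character()
  exp_sites <- setdiff(sites, control_sites)

  # provisional design: roles are placeholders, ignored in the pre period
  feeders0 <- data.frame(
    site = rep(sites, each = 2),
    feeder = paste0(rep(sites, each = 2), "_F", 1:2),
    role = ifelse(rep(sites, each = 2) %in% control_sites,
                  "control", rep(c("low", "high"), length(sites))),
    stringsAsFactors = FALSE
  )
  treatments0 <- data.frame(
    tag = pop$birds$tag, site = pop$birds$site,
    treatment = ifelse(pop$birds$site %in% control_sites,
                       "control", "unassigned"),
    stringsAsFactors = FALSE
  )
  design0 <- experiment_design(feeders0, treatments0,
                               config$days_pre, config$days_exp)

  pre <- simulate_visits(pop, config, design0, period = "pre")

  pre_counts <- stats::aggregate(
    list(reads = pre$visits$time),
    by = list(site = pre$visits$site, feeder = pre$visits$feeder),
    FUN = length
  )
  # feeders with zero pre reads still need a row
  miss <- !(feeders0$feeder %in% pre_counts$feeder)
  if (any(miss)) {
    pre_counts <- rbind(pre_counts,
                        data.frame(site = feeders0$site[miss],
                                   feeder = feeders0$feeder[miss],
                                   reads = 0L))
  }
  roles <- assign_feeder_roles(pre_counts, exp_sites,
                               seed = derive_seed(config$seed, 303L))

  bird_counts <- stats::aggregate(
    list(reads = pre$visits$time),
    by = list(tag = pre$visits$tag, site = pre$visits$site),
    FUN = length
  )
  unseen <- !(pop$birds$tag %in% bird_counts$tag)
  if (any(unseen)) {
    bird_counts <- rbind(bird_counts,
                         data.frame(tag = pop$birds$tag[unseen],
                                    site = pop$birds$site[unseen],
                                    reads = 0L))
  }
  treatments <- assign_bird_treatments(
    bird_counts[bird_counts$site %in% exp_sites, ],
    min_records = config$eligibility_min_reads,
    low_fraction = config$low_fraction,
    seed = derive_seed(config$seed, 404L)
  )
  if (length(control_sites)) {
    ctl <- pop$birds[pop$birds$site %in% control_sites, ]
    treatments <- rbind(treatments,
                        data.frame(tag = ctl$tag, site = ctl$site,
                                   treatment = "control",
                                   stringsAsFactors = FALSE))
  }

  design <- experiment_design(roles, treatments,
                              config$days_pre, config$days_exp)
  during <- simulate_visits(pop, config, design, period = "during")

  visits <- rbind(pre$visits, during$visits)
  visits <- visits[order(visits$feeder, visits$time), ]
  rownames(visits) <- NULL
  truth <- rbind(pre$truth, during$truth)
  truth <- truth[order(truth$feeder, truth$center), ]
  rownames(truth) <- NULL

  structure(list(visits = visits, truth = truth, design = design,
                 population = pop, config = config),
            class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf("<colony_sim> %d reads, %d planted events, %d birds\n",
              nrow(x$visits), nrow(x$truth), nrow(x$population$birds)))
  print(x$design)
  invisible(x)
}

#' Simulate one patch-discovery trial over a social network
#'
#' A network-based diffusion generator: in one-minute steps, each naive
#' bird becomes informed (arrives at the novel feeder) with hazard
#' `discovery_base * (1 + social_effect * z_i)`, where `z_i` is the sum of
#' that bird's association weights to already-informed birds. When
#' `social_effect > 0` one uniformly chosen bird is seeded informed at a
#' random step within the first tenth of the trial so transmission has a
#' source; with `social_effect = 0` discovery is socially independent and
#' no seed is planted.
#'
#' @param network Symmetric association matrix with tag dimnames.
#' @param config A [sim_config()] supplying `discovery_base` and
#'   `social_effect`.
#' @param trial_length Trial length in seconds (> 0).
#' @param seed Optional integer seed; defaults to a substream of the
#'   config master seed.
#' @return Named numeric vector of arrival times in seconds from trial
#'   start; `NA` for birds that never arrive.
#' @export
simulate_discovery_trial <- function(network, config, trial_length,
                                     seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (trial_length <= 0) {
    stop("simulate_discovery_trial: trial_length must be > 0", call. = FALSE)
  }
  tags <- rownames(network)
  if (is.null(tags) || !length(tags)) {
    stop("simulate_discovery_trial: network must have a nonempty node set",
         call. = FALSE)
  }
  set.seed(if (is.null(seed)) derive_seed(config$seed, 505L) else seed)

  n <- length(tags)
  steps <- max(1L, floor(trial_length / 60))
  informed <- rep(FALSE, n)
  arrival <- rep(NA_real_, n)

  seed_step <- 0L
  seed_bird <- 0L
  if (config$social_effect > 0) {
    seed_bird <- sample.int(n, 1)
    seed_step <- sample.int(max(1L, floor(steps / 10)), 1)
  }

  lam0 <- config$discovery_base
  s <- config$social_effect
  for (t in seq_len(steps)) {
    if (seed_step == t) {
      if (!informed[seed_bird]) {
        informed[seed_bird] <- TRUE
        arrival[seed_bird] <- t * 60
      }
    }
    naive <- which(!informed)
    if (!length(naive)) break
    z <- as.numeric(network[naive, informed, drop = FALSE] %*%
                      rep(1, sum(informed)))
    p <- 1 - exp(-lam0 * (1 + s * z))
    hit <- naive[stats::runif(length(naive)) < p]
    if (length(hit)) {
      informed[hit] <- TRUE
      arrival[hit] <- t * 60
    }
  }
  stats::setNames(arrival, tags)
}
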