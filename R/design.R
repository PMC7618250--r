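#' Construct an experiment design
#'
#' The design fixes, before the experimental period starts: the feeder
#' roles at each site (`low` / `high` at experimental sites, `control` at
#' control sites), the per-bird treatment assignments, and the period
#' boundaries. Day 1 is the first pre-experimental day; the experimental
#' period starts on day `days_pre + 1`.
#'
#' @param feeders data.frame with columns `site`, `feeder`, `role`
#'   (one of `"low"`, `"high"`, `"control"`); exactly one low and one high
#'   feeder per experimental site.
#' @param treatments data.frame with columns `tag`, `site`, `treatment`
#'   (one of `"low"`, `"high"`, `"control"`, `"unassigned"`).
#' @param days_pre,days_exp Period lengths in days.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(feeders, treatments, days_pre, days_exp) {
  stopifnot(all(c("site", "feeder", "role") %in% names(feeders)),
            all(c("tag", "site", "treatment") %in% names(treatments)),
            days_pre >= 1, days_exp >= 1)
  if (!all(feeders$role %in% c("low", "high", "control"))) {
    stop("experiment_design: feeder roles must be low/high/control",
         call. = FALSE)
  }
  if (!all(treatments$treatment %in%
           c("low", "high", "control", "unassigned"))) {
    stop("experiment_design: treatments must be low/high/control/unassigned",
         call. = FALSE)
  }
  for (s in unique(feeders$site)) {
    r <- feeders$role[feeders$site == s]
    if (!(identical(sort(r), c("high", "low")) ||
          all(r == "control"))) {
      stop(sprintf(
        "experiment_design: site '%s' must have one low + one high feeder, or all control",
        s), call. = FALSE)
    }
  }
  structure(list(feeders = feeders, treatments = treatments,
                 days_pre = as.integer(days_pre),
                 days_exp = as.integer(days_exp)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  n_exp <- length(unique(x$feeders$site[x$feeders$role != "control"]))
  n_ctl <- length(unique(x$feeders$site[x$feeders$role == "control"]))
  cat(sprintf("<experiment_design> %d experimental + %d control site(s), %d + %d days\n",
              n_exp, n_ctl, x$days_pre, x$days_exp))
  tab <- table(x$treatments$treatment)
  cat("  treatments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Period ("pre" or "during") of a study day under a design
#' @param design An [experiment_design()].
#' @param day Integer day index from study start (day 1 = first pre day).
#' @return Character vector of periods.
#' @export
design_period <- function(design, day) {
  ifelse(day <= design$days_pre, "pre", "during")
}

#' Experimental day index within its period (1-based)
#' @inheritParams design_period
#' @return Integer vector.
#' @export
design_day_index <- function(design, day) {
  ifelse(day <= design$days_pre, day, day - design$days_pre)
}

# feeder of a given role at a site ("low"/"high"); control sites have none
feeder_of_role <- function(design, site, role) {
  f <- design$feeders
  out <- f$feeder[f$site == site & f$role == role]
  if (length(out) != 1) NA_character_ else out
}
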