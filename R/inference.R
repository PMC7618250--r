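#' Fit a period-by-treatment model and extract cell contrasts
#'
#' Fits `response ~ period * treatment (+ day)` with a site-level grouping
#' effect, delegating to standard mixed-model machinery (glmmTMB) or, for
#' fast fixed-effects fits, to `glm` with site as a fixed effect. Marginal
#' means per (period, treatment) cell and Tukey-adjusted pairwise
#' comparisons come from emmeans. The response may be transformed first
#' (`inverse`, `square`, `sqrt`, `log`); the transformation is recorded
#' with the result.
#'
#' @param data data.frame with columns `period`, `treatment`, `site`, the
#'   response, and optionally `exp_day`.
#' @param response Response specification: a column name, or for binomial
#'   data a `"cbind(successes, failures)"` string.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param transformation One of `"identity"`, `"inverse"`, `"square"`,
#'   `"sqrt"`, `"log"` (gaussian responses only).
#' @param engine `"glmmTMB"` (random intercepts per grouping column) or
#'   `"glm"` (site as a fixed effect; no random effects).
#' @param random Grouping columns given random intercepts under the
#'   glmmTMB engine (default `"site"`).
#' @param include_day Add `exp_day` as a covariate when present.
#' @return List of class `contrast_table`: `fit`, `emmeans` (cell means),
#'   `contrasts` (Tukey-adjusted pairwise comparisons), `transformation`,
#'   `converged`.
#' @export
fit_period_treatment_model <- function(data, response,
                                       family = c("gaussian", "binomial",
                                                  "poisson"),
                                       transformation = c("identity",
                                                          "inverse", "square",
                                                          "sqrt", "log"),
                                       engine = c("glmmTMB", "glm"),
                                       random = "site",
                                       include_day = TRUE) {
  family <- match.arg(family)
  transformation <- match.arg(transformation)
  engine <- match.arg(engine)
  stopifnot(all(c("period", "treatment", "site") %in% names(data)))

  lhs <- response
  if (!grepl("cbind", response, fixed = TRUE)) {
    if (transformation != "identity") {
      if (family != "gaussian") {
        stop("transformations apply to gaussian responses only", call. = FALSE)
      }
      tf <- switch(transformation,
                   inverse = function(x) 1 / x,
                   square = function(x) x^2,
                   sqrt = sqrt, log = log)
      data$.resp <- tf(data[[response]])
      lhs <- ".resp"
    }
  }

  data$period <- factor(data$period, levels = c("pre", "during"))
  data$treatment <- factor(data$treatment)
  use_day <- include_day && "exp_day" %in% names(data) &&
    length(unique(data$exp_day)) > 1
  rhs <- paste("period * treatment", if (use_day) "+ exp_day" else "")

  converged <- TRUE
  random <- random[vapply(random, function(g) {
    length(unique(data[[g]])) > 1
  }, logical(1))]
  if (engine == "glmmTMB" && length(random)) {
    re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    form <- stats::as.formula(paste(lhs, "~", rhs, "+", re))
    fit <- withCallingHandlers(
      glmmTMB::glmmTMB(form, data = data, family = family),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (!isTRUE(fit$sdr$pdHess)) converged <- FALSE
  } else {
    extra <- if (length(unique(data$site)) > 1) "+ site" else ""
    form <- stats::as.formula(paste(lhs, "~", rhs, extra))
    fit <- stats::glm(form, data = data, family = family)
    converged <- fit$converged
  }

  emm <- emmeans::emmeans(fit, ~ period * treatment)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  structure(list(fit = fit,
                 emmeans = as.data.frame(emm),
                 contrasts = as.data.frame(ctr),
                 transformation = transformation,
                 converged = converged),
            class = "contrast_table")
}

#' Extract one oriented period-treatment cell contrast
#'
#' Looks up the pairwise comparison between two (period, treatment) cells
#' in a [fit_period_treatment_model()] result and returns it oriented as
#' cell A minus cell B regardless of the order emmeans stored it in.
#'
#' @param ct A `contrast_table`.
#' @param period_a,treatment_a First cell.
#' @param period_b,treatment_b Second cell.
#' @return List with `estimate` (A - B, on the model/link scale) and
#'   `p_value` (Tukey-adjusted).
#' @export
cell_contrast <- function(ct, period_a, treatment_a, period_b, treatment_b) {
  stopifnot(inherits(ct, "contrast_table"))
  a <- paste(period_a, treatment_a)
  b <- paste(period_b, treatment_b)
  cc <- ct$contrasts
  fwd <- cc$contrast == paste(a, "-", b)
  rev <- cc$contrast == paste(b, "-", a)
  if (sum(fwd) + sum(rev) != 1) {
    stop(sprintf("cell_contrast: comparison '%s vs %s' not found", a, b),
         call. = FALSE)
  }
  if (any(fwd)) {
    list(estimate = cc$estimate[fwd], p_value = cc$p.value[fwd])
  } else {
    list(estimate = -cc$estimate[rev], p_value = cc$p.value[rev])
  }
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("<contrast_table> transformation = %s, converged = %s\n",
              x$transformation, x$converged))
  print(x$contrasts, digits = 3)
  invisible(x)
}

# adjusted (period x treatment) cell means via a no-intercept cell factor;
# pairwise differences of cell coefficients are the adjusted contrasts
.cell_fit <- function(y, X, qr_X) {
  co <- qr.coef(qr_X, y)
  co[is.na(co)] <- 0
  co
}

#' Node-permutation significance test for network-position metrics
#'
#' Tests period-by-treatment contrasts on a per-bird network metric against
#' a null in which node identities are shuffled within each site-period
#' network while the network structure (hence the multiset of metric
#' values per site-period) is held fixed. Per permutation the model is
#' refitted and each pairwise cell contrast stored; the two-tailed p-value
#' per contrast is `(1 + #{|null| >= |observed|}) / (n_perm + 1)`. A
#' contrast is significant at the 5% level when the observed coefficient
#' falls outside the central 95% of its null distribution.
#'
#' The refitted model is a reduced fixed-effects linear model — a
#' no-intercept (period x treatment) cell factor plus additive site (and
#' optional covariate) terms — so that each permutation costs one
#' least-squares solve against a fixed design.
#'
#' @param metrics data.frame with `tag`, `site`, `period`, `treatment`, and
#'   the metric column named by `value`.
#' @param value Name of the metric column.
#' @param n_perm Number of node permutations (default 1000).
#' @param seed Integer seed.
#' @param covariates Optional character vector of additional additive
#'   model columns.
#' @return List of class `permutation_result`: `observed` (named contrast
#'   vector), `null` (n_perm x contrasts matrix), `p` (named vector),
#'   `n_perm`, `seed`.
#' @export
node_permutation_test <- function(metrics, value, n_perm = 1000, seed = 1,
                                  covariates = NULL) {
  stopifnot(all(c("tag", "site", "period", "treatment", value)
                %in% names(metrics)))
  if (n_perm < 100) {
    warning(sprintf("node_permutation_test: n_perm = %d is small", n_perm))
  }
  d <- metrics[!is.na(metrics[[value]]), , drop = FALSE]
  n_dropped <- nrow(metrics) - nrow(d)
  if (n_dropped > 0) {
    message(sprintf("node_permutation_test: dropped %d bird(s) with missing metric",
                    n_dropped))
  }
  d$period <- factor(d$period, levels = intersect(c("pre", "during"),
                                                  unique(d$period)))
  d$treatment <- factor(d$treatment)
  cell <- interaction(d$period, d$treatment, sep = ":", drop = TRUE)
  if (nlevels(cell) < 2) {
    stop("node_permutation_test: need at least two period:treatment cells",
         call. = FALSE)
  }

  rhs <- "~ 0 + .cell"
  d$.cell <- cell
  if (length(unique(d$site)) > 1) rhs <- paste(rhs, "+ site")
  for (cv in covariates) rhs <- paste(rhs, "+", cv)
  X <- stats::model.matrix(stats::as.formula(rhs), data = d)
  qr_X <- qr(X)
  cell_cols <- grep("^\\.cell", colnames(X))
  cell_names <- sub("^\\.cell", "", colnames(X)[cell_cols])

  pairs <- utils::combn(seq_along(cell_cols), 2)
  contrast_names <- apply(pairs, 2, function(p) {
    paste(cell_names[p[1]], "-", cell_names[p[2]])
  })
  get_contrasts <- function(y) {
    co <- .cell_fit(y, X, qr_X)[cell_cols]
    apply(pairs, 2, function(p) co[p[1]] - co[p[2]])
  }

  y <- d[[value]]
  observed <- stats::setNames(get_contrasts(y), contrast_names)

  # shuffling node identities within a site-period network == permuting the
  # metric values among that network's birds, design held fixed
  strata <- split(seq_len(nrow(d)), interaction(d$site, d$period, drop = TRUE))
  set.seed(seed)
  null <- matrix(NA_real_, n_perm, length(contrast_names),
                 dimnames = list(NULL, contrast_names))
  for (b in seq_len(n_perm)) {
    yb <- y
    for (idx in strata) {
      if (length(idx) > 1) yb[idx] <- y[sample(idx)]
    }
    null[b, ] <- get_contrasts(yb)
  }
  p <- vapply(seq_along(observed), function(j) {
    (1 + sum(abs(null[, j]) >= abs(observed[j]))) / (n_perm + 1)
  }, numeric(1))
  names(p) <- contrast_names

  structure(list(observed = observed, null = null, p = p,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations\n", x$n_perm))
  print(data.frame(contrast = names(x$observed),
                   observed = unname(x$observed),
                   p = unname(x$p)), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Patch-discovery models
#'
#' Three period-by-treatment fits on the discovery records: a binomial
#' model of whether a bird discovered a novel feeder, a linear model of the
#' log-transformed arrival order, and a linear model of the square-root
#' transformed latency (the latter two on discoverers only), each with the
#' grouping structure delegated to the chosen engine.
#'
#' @param records DiscoveryRecord data.frame (`tag`, `site`, `period`,
#'   `treatment`, `discovered`, `order`, `latency`).
#' @param engine `"glmmTMB"` or `"glm"` (see
#'   [fit_period_treatment_model()]).
#' @return List with elements `discovery`, `order`, `latency` (each a
#'   `contrast_table` or `NULL` when too few records), and `separation`
#'   (TRUE when some period:treatment cell is all- or none-discovered).
#' @export
discovery_models <- function(records, engine = c("glmmTMB", "glm")) {
  engine <- match.arg(engine)
  stopifnot(all(c("tag", "site", "period", "treatment", "discovered")
                %in% names(records)))
  records$disc <- as.integer(records$discovered)

  cellmeans <- tapply(records$disc,
                      interaction(records$period, records$treatment,
                                  drop = TRUE), mean)
  separation <- any(cellmeans %in% c(0, 1))
  if (separation) {
    warning("discovery_models: complete separation in some period:treatment cell")
  }

  disc_fit <- fit_period_treatment_model(records, "disc",
                                         family = "binomial",
                                         engine = engine,
                                         random = c("tag", "site"),
                                         include_day = FALSE)
  found <- records[records$discovered & !is.na(records$order), , drop = FALSE]
  order_fit <- NULL
  latency_fit <- NULL
  if (nrow(found) >= 8 &&
      nlevels(interaction(found$period, found$treatment, drop = TRUE)) >= 2) {
    order_fit <- fit_period_treatment_model(found, "order",
                                            family = "gaussian",
                                            transformation = "log",
                                            engine = engine,
                                            random = c("tag", "site"),
                                            include_day = FALSE)
    latency_fit <- fit_period_treatment_model(found, "latency",
                                              family = "gaussian",
                                              transformation = "sqrt",
                                              engine = engine,
                                              random = c("tag", "site"),
                                              include_day = FALSE)
  }
  list(discovery = disc_fit, order = order_fit, latency = latency_fit,
       separation = separation)
}
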