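#' Reliable intervals from a per-sample t-value series
#'
#' Sample-wise model fits yield one t-value per time sample. An effect is
#' considered reliable wherever the t-values exceed `threshold` for at least
#' `min_run_ms` of consecutive samples (default: |t| > 2 for at least 200 ms
#' on a 1 ms grid). No p-values are attached to the sweep; this run-length
#' rule is the reliability criterion.
#'
#' @param t_values Per-sample t-values (`NA` = not estimable, never counts as
#'   exceeding).
#' @param t_ms Time stamps of the samples, ms; must be a uniform grid.
#' @param threshold t-value threshold (default 2).
#' @param min_run_ms Minimum run duration in ms (default 200).
#' @param sided `"two"` (default: |t| > threshold; post-saccadic constriction
#'   gives negative coefficients under the usual reference levels) or
#'   `"one"` (signed t > threshold).
#' @return Data frame with columns `start_ms`, `end_ms` — maximal qualifying
#'   runs as half-open intervals `[start_ms, end_ms)` in grid units —
#'   disjoint and sorted; zero rows if none qualify.
#' @export
reliable_intervals <- function(t_values, t_ms, threshold = 2,
                               min_run_ms = 200, sided = c("two", "one")) {
  sided <- match.arg(sided)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  if (!length(t_values)) return(empty)
  if (length(t_values) != length(t_ms)) stop("t_values and t_ms lengths differ")
  step <- if (length(t_ms) > 1) diff(t_ms)[1] else 1
  if (length(t_ms) > 1 && any(diff(t_ms) != step))
    stop("t_ms must be a uniform grid")
  exceed <- if (sided == "two") !is.na(t_values) & abs(t_values) > threshold
            else !is.na(t_values) & t_values > threshold
  min_run <- ceiling(min_run_ms / step)
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(empty)
  data.frame(start_ms = t_ms[starts[keep]],
             end_ms = t_ms[ends[keep]] + step)
}

# factor coding used by the default sweep models: condition with the
# no-percept reference, saccade direction collapsed to its axis with the
# horizontal reference
sweep_factors <- function(df) {
  df$condition <- factor(df$condition,
                         levels = c("no_percept", "intrasaccadic_percept"))
  if (!"axis" %in% names(df))
    df$axis <- factor(direction_axis(df$direction),
                      levels = c("horizontal", "vertical"))
  df$participant <- factor(df$participant)
  df
}

#' Sample-wise linear mixed-effects sweep
#'
#' Fits the same linear mixed-effects model separately for every time sample
#' of the epoch grid: normalized pupil size as dependent measure, the
#' requested fixed effects, and a by-participant random intercept plus
#' by-participant random slopes for all predictors (uncorrelated random
#' effects, REML, via \pkg{lme4}). For each sample and fixed effect the
#' coefficient estimate, its standard error and t = estimate / SE are stored;
#' reliable intervals per effect follow from [reliable_intervals()].
#'
#' Samples whose full model fails to converge are refit with the random
#' slopes dropped (intercept only) and flagged `degraded`; samples where even
#' that fails are flagged and treated as unreliable.
#'
#' The grid may be coarsened with `decimate` for desk-scale runs: every
#' `decimate`-th millisecond is fitted and the run-length criterion counts
#' duration in ms, so the reliability rule is unchanged up to grid
#' resolution.
#'
#' @param epochs_df Long-format epochs as written by [write_epochs()]:
#'   columns `participant`, `trial`, `condition`, `direction`, `t_ms`,
#'   `pupil`. At least 3 participants, each contributing both condition
#'   levels (checked when `condition` is a model term).
#' @param fixed One-sided formula of fixed effects over the trial factors,
#'   e.g. `~ condition * axis` (the default; `axis` is the saccade axis,
#'   reference horizontal, and `condition` has reference `no_percept`) or
#'   `~ condition`.
#' @param decimate Grid decimation factor in ms (default 1 = every sample).
#' @param threshold,min_run_ms,sided Reliability rule, see
#'   [reliable_intervals()].
#' @return An object of class `sweep_result`: list with `table` (long data
#'   frame: `t_ms`, `term`, `estimate`, `se`, `t`, `degraded`), `intervals`
#'   (named list of interval data frames, one per fixed-effect term),
#'   `fixed`, `threshold`, `min_run_ms`.
#' @export
lme_sweep <- function(epochs_df, fixed = ~ condition * axis, decimate = 1,
                      threshold = 2, min_run_ms = 200,
                      sided = c("two", "one")) {
  sided <- match.arg(sided)
  df <- sweep_factors(as.data.frame(epochs_df))
  if (nlevels(droplevels(df$participant)) < 2)
    stop("need at least 2 participants for a mixed model (3+ recommended)")
  terms_rhs <- attr(stats::terms(fixed), "term.labels")
  if ("condition" %in% all.vars(fixed)) {
    both <- tapply(as.integer(df$condition), df$participant,
                   function(z) length(unique(z)))
    if (any(stats::na.omit(both) < 2))
      stop("every participant must contribute both condition levels")
  }
  rhs <- paste(terms_rhs, collapse = " + ")
  if (!nzchar(rhs)) rhs <- "1"
  full_f <- stats::as.formula(
    paste0("pupil ~ ", rhs, " + (1 + ", rhs, " || participant)"))
  fallback_f <- stats::as.formula(paste0("pupil ~ ", rhs, " + (1 | participant)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE, optimizer = "bobyqa",
                            check.conv.singular = "ignore")

  grid <- sort(unique(df$t_ms))
  if (decimate > 1) grid <- grid[(grid - grid[1]) %% decimate == 0]
  df <- df[df$t_ms %in% grid & !is.na(df$pupil), ]
  by_t <- split(seq_len(nrow(df)), df$t_ms)

  # a convergence warning counts as a failed fit: fall back and flag
  quiet_fit <- function(f, d) {
    ok <- TRUE
    m <- tryCatch(
      withCallingHandlers(
        suppressMessages(lme4::lmer(f, data = d, REML = TRUE, control = ctrl)),
        warning = function(w) {
          ok <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!ok) m <- NULL
    m
  }
  fit_one <- function(d) {
    m <- quiet_fit(full_f, d)
    degraded <- FALSE
    if (is.null(m)) {
      degraded <- TRUE
      m <- quiet_fit(fallback_f, d)
    }
    if (is.null(m)) return(list(co = NULL, degraded = TRUE))
    co <- summary(m)$coefficients
    list(co = co, degraded = degraded)
  }

  term_names <- NULL
  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    tt <- grid[k]
    idx <- by_t[[as.character(tt)]]
    res <- if (length(idx)) fit_one(df[idx, ]) else list(co = NULL, degraded = TRUE)
    if (is.null(term_names) && !is.null(res$co))
      term_names <- setdiff(rownames(res$co), "(Intercept)")
    if (!is.null(res$co)) {
      tn <- setdiff(rownames(res$co), "(Intercept)")
      rows[[k]] <- data.frame(t_ms = tt, term = tn,
                              estimate = res$co[tn, "Estimate"],
                              se = res$co[tn, "Std. Error"],
                              t = res$co[tn, "t value"],
                              degraded = res$degraded, row.names = NULL)
    } else {
      rows[[k]] <- data.frame(t_ms = tt, term = NA_character_,
                              estimate = NA_real_, se = NA_real_, t = NA_real_,
                              degraded = TRUE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(term_names)) term_names <- character(0)
  intervals <- lapply(term_names, function(tn) {
    sub <- tab[!is.na(tab$term) & tab$term == tn, ]
    sub <- sub[order(sub$t_ms), ]
    tv <- sub$t
    tv[sub$degraded] <- NA_real_   # degraded samples never count as reliable
    reliable_intervals(tv, sub$t_ms, threshold, min_run_ms, sided)
  })
  names(intervals) <- term_names
  structure(list(table = tab, intervals = intervals, fixed = fixed,
                 threshold = threshold, min_run_ms = min_run_ms),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d samples x %d term(s); |t| > %g for >= %g ms\n",
              length(unique(x$table$t_ms)), length(x$intervals),
              x$threshold, x$min_run_ms))
  for (tn in names(x$intervals)) {
    iv <- x$intervals[[tn]]
    if (!nrow(iv)) cat(sprintf("  %-40s no reliable interval\n", tn))
    else cat(sprintf("  %-40s reliable %s\n", tn,
                     paste(sprintf("[%g, %g) ms", iv$start_ms, iv$end_ms),
                           collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a sweep result to JSON
#'
#' @param x A `sweep_result`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sweep_result <- function(x, file) {
  jsonlite::write_json(
    list(threshold = x$threshold, min_run_ms = x$min_run_ms,
         fixed = deparse(x$fixed), intervals = x$intervals, table = x$table),
    file, dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' Select trials below the within-group median of a metric
#'
#' Post-hoc subsetting rule: within each participant x saccade-direction
#' group, keep the trials whose metric is strictly below the group's median.
#' Applied to peak-velocity error and to peak orthogonal velocity to isolate
#' the trials on which the intrasaccadic percept should have been strongest.
#'
#' @param df Data frame of trials.
#' @param metric Name of the numeric metric column.
#' @param group_cols Grouping columns (default participant and direction).
#' @return The selected subset of `df`. Groups with fewer than 2 trials are
#'   skipped with a warning (none of their trials selected).
#' @export
median_split_select <- function(df, metric,
                                group_cols = c("participant", "direction")) {
  g <- interaction(df[group_cols], drop = TRUE)
  keep <- logical(nrow(df))
  for (lev in levels(g)) {
    sel <- which(g == lev)
    if (length(sel) < 2) {
      warning("group ", lev, " has < 2 trials; skipped")
      next
    }
    v <- df[[metric]][sel]
    keep[sel] <- !is.na(v) & v < stats::median(v, na.rm = TRUE)
  }
  df[keep, , drop = FALSE]
}

#' Two-sided paired-samples t-test
#'
#' Classical paired t-test on per-participant scalars (df = n - 1), used for
#' the post-hoc comparisons of saccade-kinematic dispersion between axes.
#'
#' @param values_a,values_b Equal-length numeric vectors paired by
#'   participant, n >= 2.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("paired vectors differ in length")
  if (length(values_a) < 2) stop("need at least 2 pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences; t is undefined")
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Per-participant dispersion metrics of saccade kinematics
#'
#' For each participant: the sample standard deviation (n - 1 denominator) of
#' peak saccade velocity, and the mean peak orthogonal velocity. These are
#' the dependent measures of the paired axis comparisons.
#'
#' @param df Trial data frame with columns `participant`, `peak_velocity`,
#'   `peak_orthogonal_velocity`.
#' @return Data frame with `participant`, `sd_peak_velocity`,
#'   `mean_orthogonal_velocity`, one row per participant with >= 2 trials
#'   (others skipped with a warning).
#' @export
dispersion_metrics <- function(df) {
  out <- lapply(split(df, df$participant), function(d) {
    if (nrow(d) < 2) {
      warning("participant ", d$participant[1], " has < 2 trials; skipped")
      return(NULL)
    }
    data.frame(participant = d$participant[1],
               sd_peak_velocity = stats::sd(d$peak_velocity),
               mean_orthogonal_velocity = mean(d$peak_orthogonal_velocity))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
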