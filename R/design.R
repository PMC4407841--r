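# Trial design: treatment-set structure, schedule arithmetic, block
# randomization of period order, and the distribution-based MCID rule.

#' Trial design specification
#'
#' Defaults encode the mexiletine N-of-1 series design: 30 patients split
#' 15/15 into chloride- and sodium-channelopathy subgroups, up to 4 treatment
#' sets per patient, each set being a 4-week active and a 4-week placebo
#' period separated by a 1-week washout and followed by 2 analysis weeks
#' (11 weeks per set), with 10 diary observations per arm per treatment pair
#' retained for analysis.
#'
#' @param n_patients number of patients in the cohort.
#' @param subgroup_split named integer vector of patients per subgroup; must
#'   sum to \code{n_patients}.
#' @param max_sets maximum number of treatment sets per patient.
#' @param period_weeks length of each treatment period, weeks.
#' @param washout_weeks washout between the two periods of a set, weeks.
#' @param analysis_weeks interim-analysis window at the end of a set, weeks.
#' @param diary_days_per_period scheduled daily diary calls per period (the
#'   last two weeks of each 4-week period).
#' @param obs_per_arm_per_pair diary observations per arm per treatment pair
#'   assumed in analysis and simulation (anticipated missingness reduces the
#'   14 scheduled calls to 10 modeled observations).
#' @return an object of class \code{design_spec}.
#' @export
design_spec <- function(n_patients = 30L,
                        subgroup_split = c(chloride = 15L, sodium = 15L),
                        max_sets = 4L,
                        period_weeks = 4L,
                        washout_weeks = 1L,
                        analysis_weeks = 2L,
                        diary_days_per_period = 14L,
                        obs_per_arm_per_pair = 10L) {
  vals <- c(n_patients, max_sets, period_weeks, washout_weeks,
            analysis_weeks, diary_days_per_period, obs_per_arm_per_pair)
  if (any(!is.finite(vals)) || any(vals < 1))
    stop("all design counts and durations must be strictly positive",
         call. = FALSE)
  if (is.null(names(subgroup_split)) || any(!nzchar(names(subgroup_split))))
    stop("subgroup_split must be a named vector", call. = FALSE)
  if (any(subgroup_split < 0))
    stop("subgroup counts must be non-negative", call. = FALSE)
  if (sum(subgroup_split) != n_patients)
    stop("subgroup_split must sum to n_patients", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 subgroup_split = subgroup_split,
                 max_sets = as.integer(max_sets),
                 period_weeks = as.integer(period_weeks),
                 washout_weeks = as.integer(washout_weeks),
                 analysis_weeks = as.integer(analysis_weeks),
                 diary_days_per_period = as.integer(diary_days_per_period),
                 obs_per_arm_per_pair = as.integer(obs_per_arm_per_pair)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("N-of-1 trial design: %d patients (%s), up to %d sets\n",
              x$n_patients,
              paste(sprintf("%s %d", names(x$subgroup_split),
                            x$subgroup_split), collapse = ", "),
              x$max_sets))
  cat(sprintf("  per set: %d + %d + %d + %d weeks (period/washout/period/analysis)\n",
              x$period_weeks, x$washout_weeks, x$period_weeks,
              x$analysis_weeks))
  invisible(x)
}

#' Build a week-by-week trial schedule
#'
#' Lays out \code{n_sets} consecutive treatment sets as contiguous 1-based
#' week ranges: period 1, washout, period 2, then the analysis window. With
#' defaults each set spans 11 weeks, so the full schedule runs 11 to 44
#' weeks per patient.
#'
#' @param n_sets number of treatment sets, between 1 and \code{design$max_sets}.
#' @param design a \code{\link{design_spec}}.
#' @return an object of class \code{nof1_schedule}: a list with \code{sets}
#'   (one record per set, each holding integer week ranges) and
#'   \code{total_weeks}.
#' @examples
#' build_schedule(1)$total_weeks  # 11
#' build_schedule(4)$total_weeks  # 44
#' @export
build_schedule <- function(n_sets, design = design_spec()) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.numeric(n_sets) || length(n_sets) != 1L || is.na(n_sets) ||
      n_sets != round(n_sets) || n_sets < 1 || n_sets > design$max_sets)
    stop(sprintf("invalid design: n_sets must be an integer in [1, %d]",
                 design$max_sets), call. = FALSE)
  n_sets <- as.integer(n_sets)
  span <- 2L * design$period_weeks + design$washout_weeks +
    design$analysis_weeks
  sets <- vector("list", n_sets)
  wk <- 1L
  for (s in seq_len(n_sets)) {
    p1 <- wk:(wk + design$period_weeks - 1L)
    wash <- (wk + design$period_weeks):(wk + design$period_weeks +
                                          design$washout_weeks - 1L)
    p2 <- (max(wash) + 1L):(max(wash) + design$period_weeks)
    an <- (max(p2) + 1L):(max(p2) + design$analysis_weeks)
    sets[[s]] <- list(set = s, period1_weeks = p1, washout_weeks = wash,
                      period2_weeks = p2, analysis_weeks = an)
    wk <- max(an) + 1L
  }
  structure(list(sets = sets, total_weeks = n_sets * span,
                 weeks_per_set = span),
            class = "nof1_schedule")
}

#' @export
print.nof1_schedule <- function(x, ...) {
  cat(sprintf("Schedule: %d treatment set(s), %d weeks total\n",
              length(x$sets), x$total_weeks))
  for (s in x$sets)
    cat(sprintf("  set %d: period1 wk %d-%d | washout wk %d | period2 wk %d-%d | analysis wk %d-%d\n",
                s$set, min(s$period1_weeks), max(s$period1_weeks),
                min(s$washout_weeks), min(s$period2_weeks),
                max(s$period2_weeks), min(s$analysis_weeks),
                max(s$analysis_weeks)))
  invisible(x)
}

#' Block-randomize period order within treatment sets
#'
#' Each treatment set is a block of size two (one active, one placebo
#' period); the order within each set is randomized independently with
#' probability 1/2, reproducibly under a seed. Orders are not constrained
#' across sets.
#'
#' @param n_sets number of sets to randomize.
#' @param seed integer seed; recorded in the result.
#' @return an object of class \code{period_order}: list with \code{labels}
#'   (character vector in \code{c("active_first", "placebo_first")}) and
#'   \code{seed}.
#' @export
randomize_orders <- function(n_sets, seed) {
  if (!is.numeric(n_sets) || length(n_sets) != 1L || n_sets < 1 ||
      n_sets != round(n_sets))
    stop("n_sets must be a positive integer", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  labels <- withr_seed(seed, {
    sample(c("active_first", "placebo_first"), as.integer(n_sets),
           replace = TRUE)
  })
  structure(list(labels = labels, seed = as.integer(seed)),
            class = "period_order")
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Distribution-based minimal clinically important difference (half SD)
#'
#' The MCID on the diary severity scale is taken as half the within-subject
#' standard deviation; with the previously reported within-subject SD of 1.5
#' this gives the 0.75-point MCID used throughout.
#'
#' @param within_subject_sd within-subject standard deviation, score units.
#' @return \code{within_subject_sd / 2}.
#' @examples
#' mcid_half_sd(1.5)  # 0.75
#' @export
mcid_half_sd <- function(within_subject_sd) {
  if (!is.numeric(within_subject_sd) || any(within_subject_sd < 0) ||
      any(!is.finite(within_subject_sd)))
    stop("within_subject_sd must be non-negative and finite", call. = FALSE)
  within_subject_sd / 2
}
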