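VALID_ROUTES <- c("oral", "IM", "IV", "topical")
SYSTEMIC_ROUTES <- c("oral", "IM", "IV")

check_exposure_log <- function(log) {
  stopifnot(all(c("subject_id", "route", "start_day", "duration_days") %in% names(log)))
  bad <- setdiff(unique(log$route), VALID_ROUTES)
  if (length(bad)) {
    stop("unknown route(s): ", paste(bad, collapse = ", "),
         "; valid routes are: ", paste(VALID_ROUTES, collapse = ", "))
  }
  if (nrow(log) && (any(log$duration_days < 1) || any(log$start_day < 0))) {
    stop("courses require start_day >= 0 and duration_days >= 1")
  }
  invisible(log)
}

# Days covered by the courses in `rows`, as a set of integer ages,
# clipped to [0, cutoff_day).
course_day_union <- function(rows, cutoff_day = Inf) {
  if (!nrow(rows)) return(integer(0))
  days <- unlist(lapply(seq_len(nrow(rows)), function(i) {
    seq(rows$start_day[i], rows$start_day[i] + rows$duration_days[i] - 1L)
  }))
  unique(days[days >= 0 & days < cutoff_day])
}

#' Build per-subject antibiotic exposure variables
#'
#' From a prescription log, derives the exposure variables used for
#' hypothesis testing. Topical courses are excluded from every variable.
#' Cumulative oral exposure is the number of distinct days of life covered
#' by oral courses before `cutoff_day` (overlapping courses are not double
#' counted). "Use at birth" is any systemic (oral/IM/IV) course starting
#' within the first `birth_window_days` days of life.
#'
#' @param log Exposure log: subject_id, route, start_day, duration_days.
#' @param subjects Optional vector of subject ids to report (subjects with
#'   no courses get zero exposure); defaults to subjects present in the log.
#' @param cutoff_day Upper bound (exclusive) for cumulative days, default 365.
#' @param birth_window_days Width of the birth window in days, default 7.
#' @return Data frame: subject_id, used_at_birth, cumulative_oral_days,
#'   n_oral_courses, n_systemic_courses.
#' @export
build_exposure_variables <- function(log, subjects = NULL, cutoff_day = 365,
                                     birth_window_days = 7) {
  check_exposure_log(log)
  subjects <- sort(unique(subjects %||% log$subject_id))
  sys <- log[log$route %in% SYSTEMIC_ROUTES, , drop = FALSE]
  out <- lapply(subjects, function(s) {
    rows <- sys[sys$subject_id == s, , drop = FALSE]
    oral <- rows[rows$route == "oral", , drop = FALSE]
    data.frame(
      subject_id = s,
      used_at_birth = any(rows$start_day <= birth_window_days),
      cumulative_oral_days = length(course_day_union(oral, cutoff_day)),
      n_oral_courses = nrow(oral),
      n_systemic_courses = nrow(rows),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Cumulative oral antibiotic days up to an age
#' @inheritParams build_exposure_variables
#' @param day Age cutoff in days (exclusive).
#' @return Named integer vector of cumulative oral days per subject.
#' @export
cumulative_oral_days <- function(log, subjects = NULL, day = 365) {
  check_exposure_log(log)
  subjects <- sort(unique(subjects %||% log$subject_id))
  oral <- log[log$route == "oral", , drop = FALSE]
  vapply(stats::setNames(subjects, subjects), function(s) {
    length(course_day_union(oral[oral$subject_id == s, , drop = FALSE], day))
  }, integer(1))
}

#' Oral antibiotic use near a reference day
#'
#' `recent_use` flags any oral course overlapping the `window` days before
#' `day`; `current_use` flags a course covering `day` itself.
#'
#' @inheritParams cumulative_oral_days
#' @param day Reference age in days.
#' @param window Look-back width in days (7 matches "within 7 days of the
#'   sample").
#' @return Named logical vector per subject.
#' @export
recent_oral_use <- function(log, subjects = NULL, day, window = 7) {
  check_exposure_log(log)
  subjects <- sort(unique(subjects %||% log$subject_id))
  oral <- log[log$route == "oral", , drop = FALSE]
  vapply(stats::setNames(subjects, subjects), function(s) {
    d <- course_day_union(oral[oral$subject_id == s, , drop = FALSE])
    any(d >= day - window & d < day)
  }, logical(1))
}

#' @rdname recent_oral_use
#' @export
current_oral_use <- function(log, subjects = NULL, day) {
  check_exposure_log(log)
  subjects <- sort(unique(subjects %||% log$subject_id))
  oral <- log[log$route == "oral", , drop = FALSE]
  vapply(stats::setNames(subjects, subjects), function(s) {
    day %in% course_day_union(oral[oral$subject_id == s, , drop = FALSE])
  }, logical(1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, under the hypergeometric
#' null with fixed margins, the probabilities of all tables no more likely
#' than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return The exact p-value.
#' @export
fisher_exact_2x2 <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(tab != round(tab))) stop("counts must be integers")
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Summarise an exposure log
#'
#' Course counts by route and the oral fraction among all prescriptions,
#' mirroring a cohort-description table.
#'
#' @inheritParams build_exposure_variables
#' @return List: n_courses, n_subjects, courses_by_route, oral_percent.
#' @export
summarise_exposure_log <- function(log) {
  check_exposure_log(log)
  by_route <- table(factor(log$route, levels = VALID_ROUTES))
  list(
    n_courses = nrow(log),
    n_subjects = length(unique(log$subject_id)),
    courses_by_route = by_route,
    oral_percent = 100 * as.numeric(by_route["oral"]) / max(1L, nrow(log))
  )
}

#' The grouped exposure hypothesis battery
#'
#' Runs the default ten hypotheses relating antibiotic exposure to the
#' categorical vaccine response, organised in four groups for double-FDR
#' correction: cumulative oral days at 2mo/4mo/6mo/1yr (zero-inflated
#' Poisson omnibus LRT between LVR and NVR), recent use within 7 days of
#' 2mo/4mo/6mo (Fisher exact), current use at 2mo/4mo (Fisher exact), and
#' use at birth (Fisher exact).
#'
#' @param log Exposure log.
#' @param outcomes Subject-level outcome table with `subject_id`, `category`.
#' @param q Double-FDR control level (default 0.1).
#' @param timepoint_days Named vector of reference ages in days.
#' @return Data frame: hypothesis, group, test, p_raw, p_adjusted, decision.
#' @export
exposure_test_suite <- function(log, outcomes, q = 0.1,
                                timepoint_days = c("2mo" = 61, "4mo" = 122,
                                                   "6mo" = 183, "1yr" = 365)) {
  check_exposure_log(log)
  known <- outcomes[outcomes$category %in% c("LVR", "NVR"), , drop = FALSE]
  subjects <- known$subject_id
  is_lvr <- known$category == "LVR"
  rows <- list()

  fisher_p_binary <- function(flag) {
    tab <- rbind(c(sum(flag & is_lvr), sum(!flag & is_lvr)),
                 c(sum(flag & !is_lvr), sum(!flag & !is_lvr)))
    fisher_exact_2x2(tab)
  }

  for (tp in names(timepoint_days)) {
    cum <- cumulative_oral_days(log, subjects, day = timepoint_days[[tp]])
    lrt <- zip_omnibus_lrt(cum[is_lvr], cum[!is_lvr])
    rows[[length(rows) + 1L]] <- data.frame(
      hypothesis = paste0("cumulative_", tp), group = "cumulative_use",
      test = "zip_lrt", p_raw = lrt$p_value, stringsAsFactors = FALSE)
  }
  for (tp in c("2mo", "4mo", "6mo")) {
    flag <- recent_oral_use(log, subjects, day = timepoint_days[[tp]])
    rows[[length(rows) + 1L]] <- data.frame(
      hypothesis = paste0("recent_", tp), group = "recent_use",
      test = "fisher", p_raw = fisher_p_binary(flag), stringsAsFactors = FALSE)
  }
  for (tp in c("2mo", "4mo")) {
    flag <- current_oral_use(log, subjects, day = timepoint_days[[tp]])
    rows[[length(rows) + 1L]] <- data.frame(
      hypothesis = paste0("current_", tp), group = "current_use",
      test = "fisher", p_raw = fisher_p_binary(flag), stringsAsFactors = FALSE)
  }
  birth <- build_exposure_variables(log, subjects)$used_at_birth
  rows[[length(rows) + 1L]] <- data.frame(
    hypothesis = "use_at_birth", group = "use_at_birth",
    test = "fisher", p_raw = fisher_p_binary(birth), stringsAsFactors = FALSE)

  res <- do.call(rbind, rows)
  groups <- split(stats::setNames(res$p_raw, res$hypothesis), res$group)
  adj <- double_fdr(groups)
  res$p_adjusted <- adj$adjusted_p[res$hypothesis]
  res$decision <- ifelse(res$p_adjusted <= q, "significant", "ns")
  res
}
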