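#' Remove outlying titer measurements
#'
#' Within each (antigen, timepoint) group, a measurement is an outlier when
#' it lies more than three standard deviations from the group mean. The
#' pass is single-pass: mean and SD are computed over the full group,
#' including the candidate value, with the sample (n-1) SD. Values exactly
#' at three SDs are retained. Groups of size one cannot be tested and are
#' retained, flagged in the log.
#'
#' @param titers Long-format data frame with columns `subject_id`,
#'   `antigen`, `timepoint`, `value`.
#' @param n_sd Number of standard deviations defining an outlier (default 3).
#' @return List with `titers` (retained rows) and `removed` (removal log
#'   with columns subject_id, antigen, timepoint, value, reason).
#' @export
remove_outliers <- function(titers, n_sd = 3) {
  stopifnot(all(c("subject_id", "antigen", "timepoint", "value") %in% names(titers)))
  if (any(titers$value < 0, na.rm = TRUE)) stop("titer values must be non-negative")
  key <- interaction(titers$antigen, titers$timepoint, drop = TRUE)
  drop <- logical(nrow(titers))
  untestable <- logical(nrow(titers))
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- titers$value[idx]
    if (length(v) < 2) {
      untestable[idx] <- TRUE
      next
    }
    m <- mean(v)
    s <- stats::sd(v)
    if (is.na(s) || s == 0) next
    drop[idx] <- abs(v - m) > n_sd * s
  }
  removed <- titers[drop, c("subject_id", "antigen", "timepoint", "value")]
  removed$reason <- if (nrow(removed)) sprintf("more than %g SD from group mean", n_sd) else character(0)
  if (any(untestable)) {
    un <- titers[untestable, c("subject_id", "antigen", "timepoint", "value")]
    un$reason <- "group size 1: untestable, retained"
    removed <- rbind(removed, un)
  }
  list(titers = titers[!drop, , drop = FALSE], removed = removed)
}

#' Classify one subject as low or normal vaccine responder
#'
#' A subject is a low vaccine responder (LVR) when four or more of the six
#' DTaP/Hib antigen titers fall strictly below their protective thresholds.
#' With complete data, fewer than four sub-threshold titers means normal
#' responder (NVR). With missing antigens the classification is LVR if at
#' least four of the measured values are sub-threshold, NVR only when all
#' six were measured, and `unknown` otherwise.
#'
#' @param values Named numeric vector of titers for one subject at one
#'   timepoint; names are DTaP/Hib antigen identifiers.
#' @param thresholds Data frame as returned by [protective_thresholds()].
#' @param min_below Number of sub-threshold antigens defining LVR (default 4).
#' @return One of `"LVR"`, `"NVR"`, `"unknown"`.
#' @export
classify_responder <- function(values, thresholds = protective_thresholds(),
                               min_below = 4) {
  values <- values[!is.na(values)]
  if (!length(values)) return("unknown")
  unknown_ag <- setdiff(names(values), thresholds$antigen)
  if (length(unknown_ag)) {
    stop("no protective threshold for antigen(s): ",
         paste(unknown_ag, collapse = ", "))
  }
  thr <- stats::setNames(thresholds$threshold, thresholds$antigen)
  below <- sum(values < thr[names(values)])
  if (below >= min_below) return("LVR")
  if (length(values) == nrow(thresholds)) return("NVR")
  "unknown"
}

#' Classify every subject in a titer table
#'
#' @param titers Long-format titer table.
#' @param timepoint Timepoint label at which to classify (default "1yr").
#' @inheritParams classify_responder
#' @return Data frame with `subject_id`, `category`, `n_measured`, `n_below`.
#' @export
classify_responders <- function(titers, timepoint = "1yr",
                                thresholds = protective_thresholds(),
                                min_below = 4) {
  tt <- titers[titers$timepoint == timepoint &
                 titers$antigen %in% thresholds$antigen, , drop = FALSE]
  subjects <- sort(unique(titers$subject_id))
  thr <- stats::setNames(thresholds$threshold, thresholds$antigen)
  out <- lapply(subjects, function(s) {
    rows <- tt[tt$subject_id == s, , drop = FALSE]
    v <- stats::setNames(rows$value, rows$antigen)
    data.frame(subject_id = s,
               category = classify_responder(v, thresholds, min_below),
               n_measured = sum(!is.na(v)),
               n_below = sum(v < thr[names(v)], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Min-max normalize titers within antigen and timepoint
#'
#' Maps each (antigen, timepoint) group onto [0, 1] with the group minimum
#' at 0 and maximum at 1, preserving order and the shape of the
#' distribution. A constant group has no scale; all its values are set to
#' 0.5 and a warning is issued.
#'
#' @param titers Long-format titer table (outlier removal already applied).
#' @return The table with `value` replaced by the normalized value.
#' @export
minmax_normalize <- function(titers) {
  key <- interaction(titers$antigen, titers$timepoint, drop = TRUE)
  out <- titers
  degenerate <- character(0)
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- titers$value[idx]
    rng <- range(v, na.rm = TRUE)
    if (rng[1] == rng[2]) {
      out$value[idx] <- 0.5
      degenerate <- c(degenerate, g)
    } else {
      out$value[idx] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (length(degenerate)) {
    warning("degenerate (constant) min-max group(s) set to 0.5: ",
            paste(degenerate, collapse = ", "))
  }
  out
}

#' Composite vaccine-response outcomes per subject
#'
#' From min-max normalized titers at one timepoint, computes the three
#' continuous outcomes: the median across all antigens (cross-vaccine
#' titer), across the DTaP/Hib antigens, and across the PCV serotypes.
#' Medians use whatever antigens are available; a subject with no
#' measurement for a panel gets NA for that composite.
#'
#' @param normalized Long-format normalized titer table.
#' @param timepoint Timepoint label (default "1yr").
#' @return Data frame with subject_id, median_cross, median_dtap_hib,
#'   median_pcv and the antigen counts behind each median.
#' @export
composite_outcomes <- function(normalized, timepoint = "1yr") {
  tt <- normalized[normalized$timepoint == timepoint, , drop = FALSE]
  subjects <- sort(unique(normalized$subject_id))
  dt <- dtap_hib_antigens()
  pcv <- pcv_antigens()
  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  out <- lapply(subjects, function(s) {
    rows <- tt[tt$subject_id == s & !is.na(tt$value), , drop = FALSE]
    v_all <- rows$value
    v_dt <- rows$value[rows$antigen %in% dt]
    v_pcv <- rows$value[rows$antigen %in% pcv]
    data.frame(subject_id = s,
               median_cross = med(v_all),
               median_dtap_hib = med(v_dt),
               median_pcv = med(v_pcv),
               n_cross = length(v_all), n_dtap_hib = length(v_dt),
               n_pcv = length(v_pcv), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full titer-outcome stage: QC, classification and composites
#'
#' Applies outlier removal once, classifies responders at the requested
#' timepoint, min-max normalizes the retained titers, and attaches the
#' three composite outcomes.
#'
#' @inheritParams remove_outliers
#' @inheritParams composite_outcomes
#' @inheritParams classify_responder
#' @return List with `outcomes` (subject-level table combining category and
#'   composites), `outlier_log`, and `normalized` titers.
#' @export
titer_outcomes <- function(titers, timepoint = "1yr",
                           thresholds = protective_thresholds(), n_sd = 3) {
  qc <- remove_outliers(titers, n_sd = n_sd)
  cls <- classify_responders(qc$titers, timepoint, thresholds)
  norm <- minmax_normalize(qc$titers)
  comp <- composite_outcomes(norm, timepoint)
  outcomes <- merge(cls[, c("subject_id", "category")], comp,
                    by = "subject_id", all = TRUE, sort = TRUE)
  list(outcomes = outcomes, outlier_log = qc$removed, normalized = norm)
}
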