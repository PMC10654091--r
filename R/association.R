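#' Default cross-sectional timepoint windows
#'
#' Age windows (days) used to assign microbiome/metabolome samples to the
#' nominal study visits. Windows are configurable and must not overlap.
#'
#' @return Named list of c(lo, hi) day bounds with a `center` attribute.
#' @export
default_windows <- function() {
  list("2mo" = c(46, 75), "4mo" = c(107, 137),
       "6mo" = c(168, 198), "1yr" = c(335, 395))
}

window_centers <- c("2mo" = 61, "4mo" = 122, "6mo" = 183, "1yr" = 365)

check_windows <- function(windows) {
  stopifnot(is.list(windows), length(windows) >= 1)
  b <- do.call(rbind, windows)
  if (length(windows) > 1) {
    o <- order(b[, 1])
    if (any(b[o, 1][-1] <= b[o, 2][-nrow(b)])) stop("overlapping timepoint windows")
  }
  invisible(windows)
}

#' Assign a sample age to a timepoint window
#'
#' @param age_days Numeric vector of sample ages.
#' @param windows Named list of c(lo, hi) bounds (inclusive).
#' @return Character vector of window labels, NA outside all windows.
#' @export
assign_timepoint <- function(age_days, windows = default_windows()) {
  check_windows(windows)
  out <- rep(NA_character_, length(age_days))
  for (lab in names(windows)) {
    w <- windows[[lab]]
    out[age_days >= w[1] & age_days <= w[2]] <- lab
  }
  out
}

# When one subject has several samples in a window, keep the one closest
# to the window center (midpoint unless a known nominal visit age exists).
select_window_samples <- function(meta, windows = default_windows()) {
  meta$timepoint <- assign_timepoint(meta$age_days, windows)
  meta <- meta[!is.na(meta$timepoint), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(meta)),
                              list(meta$subject_id, meta$timepoint), drop = TRUE),
                        function(idx) {
    lab <- meta$timepoint[idx[1]]
    center <- if (lab %in% names(window_centers)) window_centers[[lab]]
              else mean(windows[[lab]])
    idx[which.min(abs(meta$age_days[idx] - center))]
  }))
  meta[sort(keep), , drop = FALSE]
}

#' Mann-Whitney U test between two groups
#'
#' Exact p-value by full enumeration of the rank-sum null when the
#' combined sample size is small (<= `exact_n`) and ties are absent;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_n Combined-size cutoff for the exact test (default 12).
#' @return List: statistic (U for `x`), p_value, method.
#' @export
mwu_association <- function(x, y, exact_n = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    return(list(statistic = NA_real_, p_value = NA_real_, method = "empty group"))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= exact_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # no variation anywhere: no evidence
  list(statistic = unname(wt$statistic), p_value = p,
       method = if (exact) "exact" else "normal approximation")
}

#' Spearman rank correlation between a feature and a continuous outcome
#'
#' Tie-aware (average ranks); missing pairs dropped pairwise. The p-value
#' uses the t approximation, which handles ties. A constant vector has no
#' rank ordering and yields a missing result.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum complete pairs (default 4).
#' @return List: rho, p_value, n.
#' @export
spearman_association <- function(x, y, min_n = 4) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Cross-sectional feature association screen
#'
#' For each timepoint window and each outcome, tests every feature column:
#' Mann-Whitney U against the categorical LVR/NVR outcome, Spearman rho
#' against the three continuous composite outcomes. Benjamini-Hochberg
#' correction is applied per (timepoint x outcome x assay) family —
#' never across families.
#'
#' @param features Samples x features numeric matrix.
#' @param meta Sample metadata: sample_id, subject_id, age_days.
#' @param outcomes Subject-level outcome table from [titer_outcomes()].
#' @param assay Label recorded with each result (e.g. "stool_ko").
#' @param windows Timepoint windows.
#' @param outcome_names Outcomes to test.
#' @return Data frame of association records: feature_id, outcome,
#'   timepoint, assay, statistic, rho, direction, n_used, p_raw,
#'   p_adjusted, family.
#' @export
run_association_screen <- function(features, meta, outcomes,
                                   assay = "features",
                                   windows = default_windows(),
                                   outcome_names = c("category", "median_cross",
                                                     "median_dtap_hib", "median_pcv")) {
  stopifnot(all(rownames(features) %in% meta$sample_id))
  meta <- meta[match(rownames(features), meta$sample_id), , drop = FALSE]
  sel <- select_window_samples(meta, windows)
  res <- list()
  for (tp in unique(sel$timepoint)) {
    sm <- sel[sel$timepoint == tp, , drop = FALSE]
    sub_out <- outcomes[match(sm$subject_id, outcomes$subject_id), , drop = FALSE]
    feat <- features[sm$sample_id, , drop = FALSE]
    for (oc in outcome_names) {
      fam <- paste(assay, tp, oc, sep = ":")
      recs <- lapply(colnames(feat), function(fid) {
        v <- feat[, fid]
        if (oc == "category") {
          grp <- sub_out$category
          ok <- grp %in% c("LVR", "NVR") & !is.na(v)
          x <- v[ok & grp == "LVR"]; y <- v[ok & grp == "NVR"]
          if (!length(x) || !length(y)) return(NULL)
          t <- mwu_association(x, y)
          data.frame(feature_id = fid, outcome = oc, timepoint = tp,
                     assay = assay, statistic = t$statistic, rho = NA_real_,
                     direction = sign(stats::median(x) - stats::median(y)),
                     n_used = length(x) + length(y), p_raw = t$p_value,
                     family = fam, stringsAsFactors = FALSE)
        } else {
          yv <- sub_out[[oc]]
          t <- spearman_association(v, yv)
          if (is.na(t$p_value)) return(NULL)
          data.frame(feature_id = fid, outcome = oc, timepoint = tp,
                     assay = assay, statistic = t$rho, rho = t$rho,
                     direction = sign(t$rho), n_used = t$n,
                     p_raw = t$p_value, family = fam, stringsAsFactors = FALSE)
        }
      })
      recs <- do.call(rbind, recs)
      if (is.null(recs) || !nrow(recs)) next
      recs$p_adjusted <- unname(bh_adjust(pmin(1, pmax(recs$p_raw, 1e-300))))
      res[[fam]] <- recs
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
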