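#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values: sort ascending, multiply by m/rank, take
#' the cumulative minimum from the largest rank down, cap at 1.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order (names preserved).
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::setNames(stats::p.adjust(pvalues, method = "BH"), names(pvalues))
}

#' Grouped double-FDR adjustment
#'
#' Two-stage Benjamini-Hochberg control that exploits a known grouping of
#' hypotheses (e.g. exposure variables grouped as cumulative / recent /
#' current / at-birth use). Stage 1 represents each group by its minimum
#' raw p-value and BH-adjusts those representatives across groups. Stage 2
#' BH-adjusts raw p-values within each group. The final adjusted p-value
#' of a hypothesis is the maximum of its within-group BH value and its
#' group's stage-1 value, so a hypothesis is rejected only when both its
#' group and the hypothesis itself survive. With a single group the
#' procedure reduces to plain BH.
#'
#' @param groups Named list; each element a named numeric vector of raw
#'   p-values for one group.
#' @param q Optional control level used for the returned decisions
#'   (default 0.1).
#' @return List: `adjusted_p` (named vector over all hypotheses),
#'   `group_p` (stage-1 adjusted p per group), `decision` (logical,
#'   adjusted_p <= q).
#' @export
double_fdr <- function(groups, q = 0.1) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (any(!vapply(groups, length, 1L))) stop("empty hypothesis group")
  for (g in groups) {
    if (any(is.na(g)) || any(g <= 0) || any(g > 1)) {
      stop("p-values must lie in (0, 1]")
    }
  }
  reps <- vapply(groups, min, numeric(1))
  group_p <- bh_adjust(reps)
  out <- lapply(names(groups), function(gn) {
    within <- bh_adjust(groups[[gn]])
    pmax(within, group_p[[gn]])
  })
  adjusted <- unlist(stats::setNames(out, NULL))
  names(adjusted) <- unlist(lapply(groups, names))
  raw <- unlist(lapply(groups, function(g) unname(g)))
  stopifnot(all(adjusted >= raw - 1e-12))
  list(adjusted_p = adjusted, group_p = group_p, decision = adjusted <= q)
}
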