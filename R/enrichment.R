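#' KEGG-module over-representation analysis
#'
#' One-sided Fisher exact (hypergeometric tail) test per module of whether
#' the nominally significant KOs over-represent the module, against the
#' universe of KOs detected in the experiment. Module KO sets are first
#' intersected with the detected universe; modules with fewer than five
#' detected KOs are removed before testing. BH correction runs across
#' exactly the modules tested.
#'
#' @param significant_kos Character vector of nominally significant KO ids
#'   (must be a subset of `detected_kos`).
#' @param detected_kos Character vector: all KOs detected in the experiment.
#' @param modules Data frame with columns `module_id`, `ko_id`.
#' @param min_module_size Minimum detected KOs per module (default 5).
#' @return Data frame sorted by adjusted p: module_id, k (significant KOs
#'   in module), K (detected KOs in module), n (total significant), N
#'   (total detected), p, adjusted_p, gene_ratio (k/n), k_over_K.
#' @export
module_enrichment <- function(significant_kos, detected_kos, modules,
                              min_module_size = 5) {
  stopifnot(all(c("module_id", "ko_id") %in% names(modules)))
  significant_kos <- unique(significant_kos)
  detected_kos <- unique(detected_kos)
  if (!all(significant_kos %in% detected_kos)) {
    stop("significant KOs are not a subset of detected KOs; ",
         "check the association family feeding the enrichment")
  }
  N <- length(detected_kos)
  n <- length(significant_kos)
  sets <- split(modules$ko_id, modules$module_id)
  sets <- lapply(sets, function(k) intersect(unique(k), detected_kos))
  sets <- sets[vapply(sets, length, 1L) >= min_module_size]
  if (!length(sets)) {
    return(data.frame(module_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      adjusted_p = numeric(0), gene_ratio = numeric(0),
                      k_over_K = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(sets), function(m) {
    K <- length(sets[[m]])
    k <- length(intersect(significant_kos, sets[[m]]))
    # P(X >= k) for X ~ Hypergeometric(N, K in module, n draws)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(module_id = m, k = k, K = K, n = n, N = N, p = p,
               gene_ratio = if (n > 0) k / n else 0,
               k_over_K = k / K, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- unname(bh_adjust(pmax(out$p, 1e-300)))
  out <- out[order(out$adjusted_p, out$p, out$module_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("module_id", "k", "K", "n", "N", "p", "adjusted_p",
          "gene_ratio", "k_over_K")]
}

#' Select nominally significant KOs from one association family
#'
#' @param associations Association records from [run_association_screen()],
#'   restricted to a single (timepoint x outcome x assay) family.
#' @param alpha Nominal significance level on the raw p (default 0.05).
#' @param sign_filter "any" (default), "positive" or "negative" direction.
#' @return Character vector of selected feature ids.
#' @export
select_nominal <- function(associations, alpha = 0.05,
                           sign_filter = c("any", "positive", "negative")) {
  sign_filter <- match.arg(sign_filter)
  if (length(unique(associations$family)) > 1) {
    stop("associations span multiple BH families; select one ",
         "(timepoint x outcome x assay) family first")
  }
  keep <- associations$p_raw < alpha
  if (sign_filter == "positive") keep <- keep & associations$direction > 0
  if (sign_filter == "negative") keep <- keep & associations$direction < 0
  unique(associations$feature_id[keep & !is.na(keep)])
}
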