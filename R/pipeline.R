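#' Pipeline configuration
#'
#' Bundles the paths, thresholds, windows and levels the end-to-end run
#' needs. Every analysis default (birth window, timepoint windows,
#' rarefaction depths, alpha levels) is an explicit key so the documented
#' defaults are auditable.
#'
#' @param in_dir Directory of cohort TSVs (see [write_cohort()] layout).
#' @param out_dir Output directory for result tables.
#' @param alpha Nominal significance level (default 0.05).
#' @param double_fdr_q Double-FDR control level (default 0.1).
#' @param enrichment_q BH level for module enrichment (default 0.05).
#' @param rarefaction_depths Named reads-per-sample depths per assay.
#'   The study-scale values are 2.5e6 (stool metagenome) and 1e4 (nasal
#'   16S); defaults here are desk-scale to match the synthetic generator.
#' @param windows Timepoint windows (see [default_windows()]).
#' @param birth_window_days Birth-exposure window, days.
#' @param seed Root seed; stage randomness (rarefaction) derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(in_dir, out_dir,
                            alpha = 0.05, double_fdr_q = 0.1,
                            enrichment_q = 0.05,
                            rarefaction_depths = c(stool_ko = 10000,
                                                   stool_genus = 10000,
                                                   nasal_otu = 5000),
                            windows = default_windows(),
                            birth_window_days = 7,
                            seed = 1) {
  stopifnot(alpha > 0, alpha < 1, double_fdr_q > 0, double_fdr_q < 1,
            enrichment_q > 0, enrichment_q < 1)
  check_windows(windows)
  structure(list(in_dir = in_dir, out_dir = out_dir, alpha = alpha,
                 double_fdr_q = double_fdr_q, enrichment_q = enrichment_q,
                 rarefaction_depths = rarefaction_depths, windows = windows,
                 birth_window_days = birth_window_days, seed = seed),
            class = "pipeline_config")
}

#' Validate cohort input files
#'
#' Report-only schema check: required columns, duplicate
#' (subject, antigen, timepoint) titer rows, negative titer values,
#' unknown antibiotic routes, non-positive course durations, and negative
#' feature counts, each reported with its row (or cell) location.
#'
#' @param in_dir Cohort directory.
#' @return Data frame of violations: file, row, problem. Zero rows when
#'   the inputs are clean.
#' @export
validate_inputs <- function(in_dir) {
  v <- list()
  note <- function(file, row, problem) {
    v[[length(v) + 1L]] <<- data.frame(file = file, row = row,
                                       problem = problem,
                                       stringsAsFactors = FALSE)
  }
  tp <- file.path(in_dir, "titers.tsv")
  if (file.exists(tp)) {
    ti <- read_tsv_file(tp)
    key <- paste(ti$subject_id, ti$antigen, ti$timepoint)
    dup <- which(duplicated(key))
    for (r in dup) note("titers.tsv", r, "duplicate (subject, antigen, timepoint)")
    for (r in which(ti$value < 0)) note("titers.tsv", r, "negative titer value")
  } else note("titers.tsv", NA, "missing file")
  ep <- file.path(in_dir, "exposures.tsv")
  if (file.exists(ep)) {
    ex <- read_tsv_file(ep)
    if (nrow(ex)) {
      for (r in which(!ex$route %in% VALID_ROUTES)) {
        note("exposures.tsv", r, paste0("unknown route '", ex$route[r], "'"))
      }
      for (r in which(ex$duration_days < 1)) {
        note("exposures.tsv", r, "duration_days < 1")
      }
      for (r in which(ex$start_day < 0)) note("exposures.tsv", r, "start_day < 0")
    }
  }
  for (assay in c("stool_ko", "stool_genus", "nasal_otu")) {
    fp <- file.path(in_dir, sprintf("features_%s.tsv", assay))
    if (!file.exists(fp)) next
    m <- read_cohort_matrix(fp)
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      for (i in seq_len(nrow(neg))) {
        note(basename(fp), neg[i, 1],
             sprintf("negative count at sample %s, feature %s",
                     rownames(m)[neg[i, 1]], colnames(m)[neg[i, 2]]))
      }
    }
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(file = character(0), row = integer(0),
               problem = character(0), stringsAsFactors = FALSE)
  out
}

read_cohort_matrix <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full analysis pipeline
#'
#' Executes, in order: titer QC and outcome construction; the grouped
#' antibiotic-exposure hypothesis battery with double-FDR control;
#' rarefaction and alpha/beta diversity; the cross-sectional feature and
#' metabolite association screens with per-(timepoint x outcome x assay)
#' BH correction; and KEGG-module enrichment of the nominally significant
#' stool KOs. Writes outcomes.tsv, outlier_log.tsv, exposure_tests.tsv,
#' diversity.tsv, distances_<assay>.tsv, associations.tsv, enrichment.tsv
#' and run_log.txt to the output directory. Re-running with identical
#' config and inputs reproduces the tables byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a manifest data frame (file, rows) plus the in-memory
#'   results as the `results` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("vaxbiome %s pipeline run",
                         as.character(utils::packageVersion("vaxbiome"))),
                 sprintf("seed: %d", config$seed))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  cohort <- read_cohort(config$in_dir)
  manifest <- list()
  emit <- function(x, name) {
    write_tsv_file(x, file.path(config$out_dir, name))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = name, rows = nrow(x), stringsAsFactors = FALSE)
  }

  ## stage 1: titer outcomes
  to <- titer_outcomes(cohort$titers)
  say("titers: %d measurements in, %d outliers removed, %d subjects classified",
      nrow(cohort$titers),
      sum(to$outlier_log$reason != "group size 1: untestable, retained"),
      nrow(to$outcomes))
  emit(to$outcomes, "outcomes.tsv")
  emit(to$outlier_log, "outlier_log.tsv")
  results <- list(outcomes = to$outcomes, outlier_log = to$outlier_log)

  ## stage 2: exposure tests
  if (!is.null(cohort$exposures) && nrow(cohort$exposures) > 0) {
    et <- exposure_test_suite(cohort$exposures, to$outcomes,
                              q = config$double_fdr_q)
    say("exposure: %d courses, %d hypotheses in %d groups",
        nrow(cohort$exposures), nrow(et), length(unique(et$group)))
    emit(et, "exposure_tests.tsv")
    results$exposure_tests <- et
  } else {
    say("exposure: no courses in log; exposure stage skipped")
  }

  ## stage 3: community metrics
  div_all <- list()
  for (assay in names(cohort$features)) {
    depth <- config$rarefaction_depths[[assay]]
    rar <- rarefy(cohort$features[[assay]], depth,
                  seed = substream_seed(config$seed, assay))
    say("%s: %d samples rarefied to %d reads, %d dropped below depth",
        assay, nrow(rar$table), depth, length(rar$dropped))
    if (!nrow(rar$table)) next
    div <- alpha_diversity(rar$table)
    div$assay <- assay
    div_all[[assay]] <- div
    cohort$features[[assay]] <- rar$table
    if (assay == "stool_genus") {
      d <- bray_curtis(rar$table)
      emit(cbind(data.frame(sample_id = rownames(d)), as.data.frame(d)),
           "distances_stool_genus.tsv")
      results$distances_stool_genus <- d
    }
  }
  diversity <- do.call(rbind, div_all)
  rownames(diversity) <- NULL
  emit(diversity, "diversity.tsv")
  results$diversity <- diversity

  ## stage 4: association screens
  assoc <- list()
  for (assay in names(cohort$features)) {
    if (!nrow(cohort$features[[assay]])) next
    assoc[[assay]] <- run_association_screen(
      cohort$features[[assay]], cohort$samples, to$outcomes,
      assay = assay, windows = config$windows)
  }
  # diversity metrics as features, per assay
  for (assay in names(div_all)) {
    dm <- as.matrix(div_all[[assay]][, c("richness", "shannon", "evenness")])
    rownames(dm) <- div_all[[assay]]$sample_id
    colnames(dm) <- paste(assay, colnames(dm), sep = "_")
    assoc[[paste0(assay, "_diversity")]] <- run_association_screen(
      dm, cohort$samples, to$outcomes,
      assay = paste0(assay, "_diversity"), windows = config$windows)
  }
  if (!is.null(cohort$metabolites) && nrow(cohort$metabolites)) {
    assoc$metabolite <- run_association_screen(
      cohort$metabolites, cohort$samples, to$outcomes,
      assay = "metabolite", windows = config$windows)
  }
  associations <- do.call(rbind, assoc)
  rownames(associations) <- NULL
  say("associations: %d tests in %d BH families",
      nrow(associations), length(unique(associations$family)))
  emit(associations, "associations.tsv")
  results$associations <- associations

  ## stage 5: module enrichment (stool KOs at 2mo, each outcome)
  enr_all <- list()
  ko_assoc <- associations[associations$assay == "stool_ko", , drop = FALSE]
  detected <- colnames(cohort$features$stool_ko)[
    colSums(cohort$features$stool_ko) > 0]
  for (fam in unique(ko_assoc$family[ko_assoc$timepoint == "2mo"])) {
    fa <- ko_assoc[ko_assoc$family == fam, , drop = FALSE]
    sig <- select_nominal(fa, alpha = config$alpha)
    er <- module_enrichment(sig, detected, cohort$module_map)
    if (nrow(er)) {
      er$family <- fam
      enr_all[[fam]] <- er
    }
  }
  enrichment <- do.call(rbind, enr_all)
  if (is.null(enrichment)) {
    enrichment <- data.frame(module_id = character(0))
  }
  rownames(enrichment) <- NULL
  say("enrichment: %d module tests across %d families",
      nrow(enrichment), length(enr_all))
  emit(enrichment, "enrichment.tsv")
  results$enrichment <- enrichment

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  out <- do.call(rbind, manifest)
  attr(out, "results") <- results
  invisible(out)
}
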