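#' Configuration for the synthetic infant cohort
#'
#' Defaults emulate the design of a 101-infant longitudinal cohort:
#' ~1/6 low vaccine responders at year 1, a 19-antigen titer panel with a
#' 6-member DTaP/Hib block and a 13-member PCV block (intra-PCV
#' correlation strongest), zero-inflated oral antibiotic exposure with
#' responder-group-specific components, irregular well-visit sampling with
#' dropout, and planted microbiome/metabolome signals with known effect
#' directions. Sequencing depths are desk-scale stand-ins for real depths.
#'
#' @param n_subjects Cohort size.
#' @param lvr_rate Probability a subject is a low vaccine responder (LVR)
#'   at year 1.
#' @param lvr_rate_2yr Probability of remaining LVR at year 2 (subset of
#'   year-1 LVR).
#' @param assess_rate_1yr,assess_rate_2yr Probability the titer panel is
#'   measured at each year.
#' @param titer_log_means Named vector of log-scale titer means per antigen.
#' @param titer_log_sds Named vector of log-scale SDs per antigen.
#' @param intra_pcv_correlation,intra_dtap_correlation,cross_panel_correlation
#'   Block correlations of the log-titer panel.
#' @param zip_pi,zip_lambda Named (NVR, LVR) zero-inflation probabilities
#'   and Poisson means for cumulative oral antibiotic days in year 1.
#' @param birth_exposure_rate Named (NVR, LVR) probability of a systemic
#'   course at birth.
#' @param planted_ko_effect Target Spearman rho between the planted KOs
#'   and the cross-vaccine composite titer.
#' @param planted_metabolite_effect Signed target effect for the planted
#'   metabolite.
#' @param dropout_rate Per-visit probability a scheduled visit is missed.
#' @param visit_ages Nominal well-visit ages in days.
#' @param visit_jitter Uniform jitter (+/- days) on visit ages.
#' @param n_kos,n_genera,n_otus,n_metabolites Feature-space sizes.
#' @param n_modules Number of KEGG-like modules in the synthetic map.
#' @param planted_module_size KOs in the planted module.
#' @param stool_depth,nasal_depth Reads per sample for the count tables.
#' @param seed RNG seed; the same seed and config reproduce the cohort
#'   exactly.
#' @return Validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 101,
                          lvr_rate = 12 / 72,
                          lvr_rate_2yr = 2 / 56,
                          assess_rate_1yr = 72 / 101,
                          assess_rate_2yr = 56 / 101,
                          titer_log_means = NULL,
                          titer_log_sds = NULL,
                          intra_pcv_correlation = 0.7,
                          intra_dtap_correlation = 0.4,
                          cross_panel_correlation = 0.25,
                          zip_pi = c(NVR = 0.47, LVR = 0.50),
                          zip_lambda = c(NVR = 10, LVR = 28),
                          birth_exposure_rate = c(NVR = 2 / 60, LVR = 3 / 12),
                          planted_ko_effect = 0.5,
                          planted_metabolite_effect = -0.5,
                          dropout_rate = 0.15,
                          visit_ages = c(7, 14, 21, 30, 61, 122, 183,
                                         274, 365, 456, 548, 730),
                          visit_jitter = 10,
                          n_kos = 200, n_genera = 40, n_otus = 100,
                          n_metabolites = 50,
                          n_modules = 20, planted_module_size = 8,
                          stool_depth = 20000, nasal_depth = 10000,
                          seed = 1) {
  panel <- antigen_panel()
  if (is.null(titer_log_means)) {
    thr <- protective_thresholds()
    mu <- stats::setNames(rep(log(1.5), length(panel)), panel)
    # DTaP/Hib means sit comfortably above the protective thresholds
    mu[thr$antigen] <- log(thr$threshold) + 2.8
    titer_log_means <- mu
  }
  if (is.null(titer_log_sds)) {
    titer_log_sds <- stats::setNames(rep(0.8, length(panel)), panel)
  }
  cfg <- list(n_subjects = n_subjects, lvr_rate = lvr_rate,
              lvr_rate_2yr = lvr_rate_2yr,
              assess_rate_1yr = assess_rate_1yr,
              assess_rate_2yr = assess_rate_2yr,
              antigen_panel = panel,
              titer_log_means = titer_log_means,
              titer_log_sds = titer_log_sds,
              intra_pcv_correlation = intra_pcv_correlation,
              intra_dtap_correlation = intra_dtap_correlation,
              cross_panel_correlation = cross_panel_correlation,
              zip_pi = zip_pi, zip_lambda = zip_lambda,
              birth_exposure_rate = birth_exposure_rate,
              planted_ko_effect = planted_ko_effect,
              planted_metabolite_effect = planted_metabolite_effect,
              dropout_rate = dropout_rate, visit_ages = visit_ages,
              visit_jitter = visit_jitter,
              n_kos = n_kos, n_genera = n_genera, n_otus = n_otus,
              n_metabolites = n_metabolites, n_modules = n_modules,
              planted_module_size = planted_module_size,
              stool_depth = stool_depth, nasal_depth = nasal_depth,
              seed = seed)
  props <- c(lvr_rate = lvr_rate, lvr_rate_2yr = lvr_rate_2yr,
             assess_rate_1yr = assess_rate_1yr,
             assess_rate_2yr = assess_rate_2yr,
             dropout_rate = dropout_rate, cfg$zip_pi, cfg$birth_exposure_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  R <- titer_correlation_matrix(cfg)   # errors if not PSD
  cfg$correlation <- R
  class(cfg) <- "cohort_config"
  cfg
}

# Block correlation matrix of the 19 log-titers; errors when the
# requested block correlations are not positive semi-definite.
titer_correlation_matrix <- function(cfg) {
  panel <- cfg$antigen_panel
  is_pcv <- panel %in% pcv_antigens()
  R <- matrix(cfg$cross_panel_correlation, length(panel), length(panel),
              dimnames = list(panel, panel))
  R[is_pcv, is_pcv] <- cfg$intra_pcv_correlation
  R[!is_pcv, !is_pcv] <- cfg$intra_dtap_correlation
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(paste0("titer correlation matrix is not positive ",
                        "semi-definite (min eigenvalue %.3g); adjust ",
                        "intra_pcv_correlation=%.2f, ",
                        "intra_dtap_correlation=%.2f, ",
                        "cross_panel_correlation=%.2f"),
                 min(ev), cfg$intra_pcv_correlation,
                 cfg$intra_dtap_correlation, cfg$cross_panel_correlation))
  }
  R
}

# Spearman-rho knob -> log-abundance slope for planted features.
# Calibrated once so that effect = 0.5 yields median |rho| ~ 0.5 against
# the composite at n ~ 60 under the default Dirichlet-multinomial noise.
planted_effect_slope <- function(effect) 1.3 * effect

# Split `total` exposure days into non-overlapping oral courses placed in
# [14, 364]; the union of covered days equals `total` exactly.
place_oral_courses <- function(total) {
  occupied <- integer(0)
  courses <- list()
  remaining <- total
  while (remaining > 0) {
    dur <- min(remaining, sample(3:10, 1))
    placed <- FALSE
    for (try in 1:100) {
      start <- sample(14:(364 - dur + 1), 1)
      days <- start:(start + dur - 1)
      if (!any(days %in% occupied)) {
        occupied <- c(occupied, days)
        courses[[length(courses) + 1L]] <- c(start, dur)
        placed <- TRUE
        break
      }
    }
    if (!placed) {  # dense schedule: append after the last occupied day
      start <- max(occupied) + 2L
      occupied <- c(occupied, start:(start + dur - 1))
      courses[[length(courses) + 1L]] <- c(start, dur)
    }
    remaining <- remaining - dur
  }
  courses
}

# Dirichlet-multinomial count matrix: one row per sample.
# log_weights: samples x features matrix of log relative weights.
rdirichlet_multinomial <- function(log_weights, depth, concentration) {
  t(apply(log_weights, 1, function(lw) {
    w <- exp(lw - max(lw))
    alpha <- concentration * length(lw) * w / sum(w)
    p <- stats::rgamma(length(alpha), shape = alpha)
    p <- p / sum(p)
    stats::rmultinom(1, depth, p)[, 1]
  }))
}

#' Generate a synthetic infant cohort with known ground truth
#'
#' Draws responder labels, correlated log-normal titers at 1 and 2 years
#' (LVR subjects' DTaP/Hib titers shifted below the protective thresholds
#' and verified against the threshold classifier), a zero-inflated oral
#' antibiotic exposure log with responder-specific components plus
#' at-birth IM courses and topical noise, Dirichlet-multinomial stool
#' KO/genus and nasal OTU count tables with planted KO effects, a
#' metabolite table with one planted (negative by default) signal, and a
#' synthetic KO-to-module map whose first module carries the planted KOs.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: titers, exposures, samples,
#'   features (named list of count matrices), metabolites, module_map,
#'   ground_truth, config.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  panel <- cfg$antigen_panel
  thr <- protective_thresholds()
  thr_v <- stats::setNames(thr$threshold, thr$antigen)
  units_v <- stats::setNames(thr$units, thr$antigen)
  # fixed-width ids keep lexicographic order equal to subject order
  subjects <- sprintf("SUB%05d", seq_len(max(n, 0)))

  if (n == 0) return(empty_cohort(cfg))

  lvr1 <- stats::runif(n) < cfg$lvr_rate
  keep2 <- if (cfg$lvr_rate > 0) cfg$lvr_rate_2yr / cfg$lvr_rate else 0
  lvr2 <- lvr1 & stats::runif(n) < min(1, keep2)
  assess1 <- stats::runif(n) < cfg$assess_rate_1yr
  assess2 <- stats::runif(n) < cfg$assess_rate_2yr

  Sigma <- diag(cfg$titer_log_sds[panel]) %*% cfg$correlation %*%
    diag(cfg$titer_log_sds[panel])

  draw_titers <- function(lvr_flags) {
    z <- MASS::mvrnorm(n, mu = rep(0, length(panel)), Sigma = Sigma)
    if (n == 1) z <- matrix(z, nrow = 1)
    logv <- sweep(z, 2, cfg$titer_log_means[panel], `+`)
    colnames(logv) <- panel
    # shift designated LVR subjects' DTaP/Hib titers below threshold
    for (ag in names(thr_v)) {
      logv[lvr_flags, ag] <- logv[lvr_flags, ag] -
        (cfg$titer_log_means[ag] - (log(thr_v[ag]) - 1.0))
    }
    v <- exp(logv)
    # closed loop: push any designated-LVR subject not yet labelled LVR
    # further down until the threshold rule fires
    for (i in which(lvr_flags)) {
      for (pass in 1:20) {
        if (classify_responder(v[i, names(thr_v)], thr) == "LVR") break
        v[i, names(thr_v)] <- v[i, names(thr_v)] * 0.5
      }
    }
    v
  }
  t1 <- draw_titers(lvr1)
  t2 <- draw_titers(lvr2)

  long <- function(mat, assessed, label) {
    idx <- which(assessed)
    if (!length(idx)) return(NULL)
    data.frame(
      subject_id = rep(subjects[idx], each = length(panel)),
      antigen = rep(panel, length(idx)),
      timepoint = label,
      value = as.vector(t(mat[idx, , drop = FALSE])),
      units = rep(ifelse(panel %in% names(units_v),
                         units_v[panel], "ug/mL"), length(idx)),
      stringsAsFactors = FALSE)
  }
  titers <- rbind(long(t1, assess1, "1yr"), long(t2, assess2, "2yr"))

  # latent composite response score (cross-vaccine median of min-max
  # normalized 1-year titers over the full cohort) drives planted features
  norm1 <- apply(t1, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  score <- apply(norm1, 1, stats::median)
  z_score <- as.numeric(scale(score))

  # ---- antibiotic exposure ----
  grp <- ifelse(lvr1, "LVR", "NVR")
  rows <- list()
  cum_true <- integer(n)
  for (i in seq_len(n)) {
    g <- grp[i]
    c_days <- rzip(1, cfg$zip_pi[[g]], cfg$zip_lambda[[g]])
    cum_true[i] <- c_days
    if (c_days > 0) {
      for (cr in place_oral_courses(c_days)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subjects[i], route = "oral",
          start_day = cr[1], duration_days = cr[2], stringsAsFactors = FALSE)
      }
    }
    if (stats::runif(1) < cfg$birth_exposure_rate[[g]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects[i], route = "IM",
        start_day = sample(0:5, 1), duration_days = 3L,
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < 0.25) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects[i], route = "topical",
        start_day = sample(0:700, 1), duration_days = sample(5:10, 1),
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < 0.2) {  # second-year oral course, beyond cutoff
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects[i], route = "oral",
        start_day = sample(380:700, 1), duration_days = sample(3:10, 1),
        stringsAsFactors = FALSE)
    }
  }
  exposures <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), route = character(0),
               start_day = integer(0), duration_days = integer(0))

  # ---- visit schedule and samples ----
  samp <- list()
  sid <- 0L
  add_sample <- function(subj, age, type) {
    sid <<- sid + 1L
    samp[[sid]] <<- data.frame(
      sample_id = sprintf("S%05d", sid), subject_id = subj,
      age_days = age, sample_type = type, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    ages <- cfg$visit_ages +
      sample(seq(-cfg$visit_jitter, cfg$visit_jitter), length(cfg$visit_ages),
             replace = TRUE)
    ages <- pmax(ages, 1)
    kept <- ages[stats::runif(length(ages)) >= cfg$dropout_rate]
    for (a in kept) {
      if (stats::runif(1) < 0.8) {
        add_sample(subjects[i], a, "stool_ko")
        add_sample(subjects[i], a, "stool_genus")
        if (stats::runif(1) < 0.8) add_sample(subjects[i], a, "metabolite")
      }
      add_sample(subjects[i], a, "nasal_otu")
    }
  }
  samples <- do.call(rbind, samp)

  # ---- feature tables (Dirichlet-multinomial) ----
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_kos))
  planted_kos <- sample(ko_ids, min(cfg$planted_module_size, cfg$n_kos))
  beta <- planted_effect_slope(cfg$planted_ko_effect)

  make_table <- function(type, ids, depth, conc, planted = NULL,
                         slope = 0) {
    meta <- samples[samples$sample_type == type, , drop = FALSE]
    if (!nrow(meta)) return(matrix(0L, 0, length(ids),
                                   dimnames = list(NULL, ids)))
    base <- stats::rnorm(length(ids), 0, 1.0)
    lw <- matrix(rep(base, each = nrow(meta)), nrow(meta), length(ids),
                 dimnames = list(meta$sample_id, ids))
    if (!is.null(planted) && slope != 0) {
      zi <- z_score[match(meta$subject_id, subjects)]
      lw[, planted] <- lw[, planted] + slope * zi
    }
    counts <- rdirichlet_multinomial(lw, depth, concentration = conc)
    dimnames(counts) <- list(meta$sample_id, ids)
    storage.mode(counts) <- "integer"
    counts
  }
  features <- list(
    stool_ko = make_table("stool_ko", ko_ids, cfg$stool_depth, 1.5,
                          planted = planted_kos, slope = beta),
    stool_genus = make_table("stool_genus",
                             sprintf("genus%03d", seq_len(cfg$n_genera)),
                             cfg$stool_depth, 1.5),
    nasal_otu = make_table("nasal_otu",
                           sprintf("OTU%04d", seq_len(cfg$n_otus)),
                           cfg$nasal_depth, 1.5)
  )

  # ---- metabolites (continuous, log-normal; one planted signal) ----
  met_ids <- sprintf("MET%03d", seq_len(cfg$n_metabolites))
  met_meta <- samples[samples$sample_type == "metabolite", , drop = FALSE]
  planted_met <- met_ids[1]
  met <- matrix(stats::rnorm(nrow(met_meta) * length(met_ids), 5, 1),
                nrow(met_meta), length(met_ids),
                dimnames = list(met_meta$sample_id, met_ids))
  met_beta <- planted_effect_slope(abs(cfg$planted_metabolite_effect)) *
    sign(cfg$planted_metabolite_effect)
  met[, planted_met] <- met[, planted_met] +
    met_beta * z_score[match(met_meta$subject_id, subjects)]
  metabolites <- exp(met)

  # ---- synthetic module map ----
  module_ids <- sprintf("M%05d", seq_len(cfg$n_modules + 1))
  map_rows <- list(data.frame(module_id = module_ids[1],
                              ko_id = planted_kos, stringsAsFactors = FALSE))
  others <- setdiff(ko_ids, planted_kos)
  if (length(others)) {
    for (m in 2:cfg$n_modules) {
      size <- min(sample(5:12, 1), length(others))
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        module_id = module_ids[m], ko_id = sample(others, size),
        stringsAsFactors = FALSE)
    }
    # one under-sized module to exercise the K < 5 filter
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      module_id = module_ids[cfg$n_modules + 1],
      ko_id = sample(others, min(4, length(others))),
      stringsAsFactors = FALSE)
  }
  module_map <- do.call(rbind, map_rows)

  ground_truth <- list(
    subjects = data.frame(subject_id = subjects, lvr_1yr = lvr1,
                          lvr_2yr = lvr2, assessed_1yr = assess1,
                          assessed_2yr = assess2,
                          true_cumulative_oral_days = cum_true,
                          composite_score = score,
                          stringsAsFactors = FALSE),
    zip_pi = cfg$zip_pi, zip_lambda = cfg$zip_lambda,
    planted_kos = planted_kos, planted_module = module_ids[1],
    planted_ko_effect = cfg$planted_ko_effect,
    planted_ko_direction = sign(cfg$planted_ko_effect),
    planted_metabolite = planted_met,
    planted_metabolite_effect = cfg$planted_metabolite_effect
  )

  structure(list(titers = titers, exposures = exposures, samples = samples,
                 features = features, metabolites = metabolites,
                 module_map = module_map, ground_truth = ground_truth,
                 config = cfg),
            class = "synthetic_cohort")
}

empty_cohort <- function(cfg) {
  empty_features <- function(ids) matrix(0L, 0, length(ids),
                                         dimnames = list(NULL, ids))
  structure(list(
    titers = data.frame(subject_id = character(0), antigen = character(0),
                        timepoint = character(0), value = numeric(0),
                        units = character(0), stringsAsFactors = FALSE),
    exposures = data.frame(subject_id = character(0), route = character(0),
                           start_day = integer(0), duration_days = integer(0),
                           stringsAsFactors = FALSE),
    samples = data.frame(sample_id = character(0), subject_id = character(0),
                         age_days = numeric(0), sample_type = character(0),
                         stringsAsFactors = FALSE),
    features = list(stool_ko = empty_features(sprintf("K%05d", seq_len(cfg$n_kos))),
                    stool_genus = empty_features(sprintf("genus%03d", seq_len(cfg$n_genera))),
                    nasal_otu = empty_features(sprintf("OTU%04d", seq_len(cfg$n_otus)))),
    metabolites = empty_features(sprintf("MET%03d", seq_len(cfg$n_metabolites))),
    module_map = data.frame(module_id = character(0), ko_id = character(0),
                            stringsAsFactors = FALSE),
    ground_truth = list(subjects = data.frame()),
    config = cfg), class = "synthetic_cohort")
}

#' Write a synthetic cohort to TSV files
#'
#' Emits titers.tsv, exposures.tsv, samples.tsv, one features_<assay>.tsv
#' per count table (sample_id column plus one column per feature),
#' metabolites.tsv, ko_module_map.tsv, thresholds.tsv and
#' ground_truth.json.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if missing).
#' @return Manifest data frame: file, rows (data rows, excluding header).
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_tsv_file(x, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = name, rows = nrow(x), stringsAsFactors = FALSE)
  }
  emit(cohort$titers, "titers.tsv")
  emit(cohort$exposures, "exposures.tsv")
  emit(cohort$samples, "samples.tsv")
  mat_df <- function(m) {
    df <- as.data.frame(m, check.names = FALSE)
    cbind(data.frame(sample_id = rownames(m) %||% character(0),
                     stringsAsFactors = FALSE), df)
  }
  for (assay in names(cohort$features)) {
    emit(mat_df(cohort$features[[assay]]),
         sprintf("features_%s.tsv", assay))
  }
  emit(mat_df(cohort$metabolites), "metabolites.tsv")
  emit(cohort$module_map, "ko_module_map.tsv")
  emit(protective_thresholds(), "thresholds.tsv")
  gt <- cohort$ground_truth
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest[[length(manifest) + 1L]] <- data.frame(
    file = "ground_truth.json",
    rows = if (is.data.frame(gt$subjects)) nrow(gt$subjects) else 0L,
    stringsAsFactors = FALSE)
  do.call(rbind, manifest)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing the TSV files.
#' @return List with the same tabular components as a `synthetic_cohort`.
#' @export
read_cohort <- function(dir) {
  read_mat <- function(name) {
    df <- read_tsv_file(file.path(dir, name))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    m
  }
  feats <- list()
  for (assay in c("stool_ko", "stool_genus", "nasal_otu")) {
    f <- sprintf("features_%s.tsv", assay)
    if (file.exists(file.path(dir, f))) feats[[assay]] <- read_mat(f)
  }
  list(titers = read_tsv_file(file.path(dir, "titers.tsv")),
       exposures = read_tsv_file(file.path(dir, "exposures.tsv")),
       samples = read_tsv_file(file.path(dir, "samples.tsv")),
       features = feats,
       metabolites = if (file.exists(file.path(dir, "metabolites.tsv")))
         read_mat("metabolites.tsv") else NULL,
       module_map = read_tsv_file(file.path(dir, "ko_module_map.tsv")))
}
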