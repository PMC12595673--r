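# Configuration-driven orchestration: simulate -> analyze -> report ->
# validate, with per-session caching and a single seed feeding every source
# of randomness.

#' Default pipeline configuration
#'
#' @param cohort A `cohort_spec` (default [cohort_spec()] study-scale
#'   defaults).
#' @param seed Master seed; overrides the cohort spec's seed so one value
#'   controls the whole run.
#' @return Nested list of class `pipeline_config` with `cohort`, `analysis`,
#'   `stats` and `seed` blocks.
#' @export
pipeline_config <- function(cohort = cohort_spec(), seed = cohort$seed) {
  cohort$seed <- as.integer(seed)
  structure(list(
    cohort = cohort,
    analysis = list(
      psd_window_s = c(-0.9, -0.2),
      half_bandwidth_hz = 2.9,
      n_tapers = 3,
      high_gamma = "split",
      stim_window_s = c(0.2, 0.9),
      base_window_s = c(-0.5, -0.1),
      n_cycles = 7,
      freqs_hz = NULL            # NULL = per-rate analysis bands
    ),
    stats = list(alpha_norm = 0.05, alpha = 0.05,
                 icc_log10 = FALSE, icc_strict = TRUE),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [pipeline_config()] defaults; the
#' `cohort:` block is passed to [cohort_spec()] and validated immediately, so
#' invalid settings fail before any output is written.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec_args <- raw$cohort %||% list()
  for (nm in c("epoch_window_s", "stim_rates_hz", "drug_rates_hz", "conditions")) {
    if (!is.null(spec_args[[nm]])) spec_args[[nm]] <- unlist(spec_args[[nm]])
  }
  cohort <- do.call(cohort_spec, spec_args)
  cfg <- pipeline_config(cohort, seed = raw$seed %||% cohort$seed)
  if (!is.null(raw$analysis)) cfg$analysis <- utils::modifyList(cfg$analysis, raw$analysis)
  if (!is.null(raw$stats)) cfg$stats <- utils::modifyList(cfg$stats, raw$stats)
  cfg
}

#' Simulate a cohort and optionally write it to disk
#'
#' @param config A `pipeline_config`.
#' @param out Optional output directory: epochs bundles are written under
#'   `animal/day/condition/rate`, ground truth as `ground_truth.json`.
#' @return The simulated `assr_cohort` (invisibly when `out` is given).
#' @export
run_simulate <- function(config, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$cohort
  spec$seed <- config$seed
  validate_cohort_spec(spec)
  cohort <- simulate_cohort(spec)
  if (is.null(out)) return(cohort)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$sessions)) {
    s <- cohort$sessions[[sid]]
    d <- file.path(out, s$meta$animal_id, sprintf("day%d", s$meta$day),
                   s$meta$condition, sprintf("%02dHz", s$stim_rate_hz))
    write_bundle(s, d)
  }
  jsonlite::write_json(cohort$ground_truth, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Read a simulated dataset directory back into a cohort object
#'
#' @param dir Directory produced by [run_simulate()].
#' @return An `assr_cohort` (with `ground_truth` when the JSON is present;
#'   `spec` is `NULL`).
#' @export
read_cohort_dir <- function(dir) {
  bundles <- dirname(list.files(dir, pattern = "^meta\\.json$",
                                recursive = TRUE, full.names = TRUE))
  if (!length(bundles)) stop("no epochs bundles found under ", dir)
  sessions <- list()
  read_failures <- list()
  for (b in bundles) {
    s <- tryCatch(read_bundle(b), error = function(e) e)
    if (inherits(s, "error")) {
      read_failures[[b]] <- conditionMessage(s)
      next
    }
    sessions[[s$meta$session_id %||% b]] <- s
  }
  if (!length(sessions)) stop("no readable epochs bundles under ", dir)
  if (length(read_failures)) {
    warning(length(read_failures), " bundle(s) failed to read under ", dir)
  }
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE)
  structure(list(sessions = sessions, ground_truth = gt, spec = NULL,
                 read_failures = read_failures),
            class = "assr_cohort")
}

# Per-session metric row: spontaneous band powers + ASSR metrics.
.analyze_session <- function(s, analysis) {
  spec_bands <- default_bands(analysis$high_gamma)
  sp <- psd_multitaper(s, analysis$psd_window_s, analysis$half_bandwidth_hz,
                       analysis$n_tapers)
  bp <- band_power(sp, spec_bands)
  am <- assr_metrics(s, freqs_hz = analysis$freqs_hz,
                     n_cycles = analysis$n_cycles,
                     stim_window_s = analysis$stim_window_s,
                     base_window_s = analysis$base_window_s)
  cbind(data.frame(session_id = s$meta$session_id %||% NA_character_,
                   animal = s$meta$animal_id, sex = s$meta$sex,
                   day = s$meta$day, condition = s$meta$condition,
                   rate = s$stim_rate_hz, stringsAsFactors = FALSE),
        bp, am)
}

#' Analyze a dataset and produce report tables
#'
#' Runs the spectral and ASSR metric extraction for every session (with
#' per-session CSV caching when `out` is given, so re-runs skip finished
#' sessions), then assembles the report tables: per-session spontaneous band
#' power and ASSR metrics, per-sex reliability (ICC) of every metric over the
#' baseline days, last-vs-first-day paired comparisons, baseline sex
#' comparisons, within-animal ketamine deltas and their comparisons.
#'
#' @param config A `pipeline_config`.
#' @param data An `assr_cohort` or a dataset directory from [run_simulate()].
#' @param out Optional output directory for CSVs, the run log and a config
#'   snapshot.
#' @return Object of class `assr_report`: list of data.frames
#'   (`session_metrics`, `icc`, `day_last_vs_first`, `sex_comparisons`,
#'   `ket_deltas`, `ket_comparisons`, `failures`).
#' @export
run_analyze <- function(config, data, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (inherits(data, "assr_cohort")) data else read_cohort_dir(data)
  if (!length(cohort$sessions)) stop("empty dataset: no sessions to analyze")
  cache_dir <- if (!is.null(out)) file.path(out, "sessions")
  if (!is.null(cache_dir)) dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)

  rows <- list()
  failures <- as.list(cohort$read_failures %||% list())
  for (sid in names(cohort$sessions)) {
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0(gsub("[^A-Za-z0-9_-]", "_", sid), ".rds"))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[sid]] <- readRDS(cache_file)
      log_lines <- c(log_lines, sprintf("session %s: cached", sid))
      next
    }
    t0 <- proc.time()[3]
    res <- tryCatch(.analyze_session(cohort$sessions[[sid]], config$analysis),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      log_lines <- c(log_lines, sprintf("session %s: FAILED (%s)", sid,
                                        conditionMessage(res)))
      next
    }
    rows[[sid]] <- res
    if (!is.null(cache_file)) saveRDS(res, cache_file)
    log_lines <- c(log_lines,
                   sprintf("session %s: ok (%.2f s)", sid, proc.time()[3] - t0))
  }
  if (!length(rows)) stop("all sessions failed to analyze")
  sm <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  st <- config$stats
  bands <- names(default_bands(config$analysis$high_gamma))
  metrics <- c("plf", "induced_ratio", "evoked_power", "harmonic_plf")

  base <- sm[sm$condition == "baseline", ]
  n_days_obs <- length(unique(base$day))

  # spontaneous band power per animal x day x condition (mean across rates)
  spont <- stats::aggregate(sm[, bands],
                            by = list(animal = sm$animal, sex = sm$sex,
                                      day = sm$day, condition = sm$condition),
                            FUN = mean)

  # reliability over baseline days, per sex
  icc_rows <- list()
  if (n_days_obs >= 2 && nrow(base) > 0) {
    sb <- spont[spont$condition == "baseline", ]
    for (b in bands) {
      icc_rows[[length(icc_rows) + 1]] <- tryCatch(
        icc_table(sb, b, strict = st$icc_strict,
                  log10_transform = st$icc_log10, alpha = st$alpha),
        error = function(e) NULL)
    }
    for (r in unique(base$rate)) for (mt in metrics) {
      d <- base[base$rate == r & !is.na(base[[mt]]), ]
      if (!nrow(d)) next
      tb <- tryCatch(icc_table(d, mt, strict = st$icc_strict,
                               log10_transform = st$icc_log10,
                               alpha = st$alpha),
                     error = function(e) NULL)
      if (!is.null(tb)) { tb$rate <- r; icc_rows[[length(icc_rows) + 1]] <- tb }
    }
  }
  icc_df <- if (length(icc_rows)) {
    out_icc <- lapply(icc_rows, function(x) { if (is.null(x$rate)) x$rate <- NA; x })
    do.call(rbind, out_icc)
  } else data.frame()

  # day last vs day 1 (paired), per sex x rate, on PLF
  dvd <- list()
  if (n_days_obs >= 2) {
    d1 <- min(base$day); dn <- max(base$day)
    for (r in unique(base$rate)) for (sx in unique(base$sex)) {
      a <- base[base$rate == r & base$sex == sx & base$day == dn, ]
      b1 <- base[base$rate == r & base$sex == sx & base$day == d1, ]
      common <- intersect(a$animal, b1$animal)
      if (length(common) < 3) next
      cmp <- tryCatch(route_test(a$plf[match(common, a$animal)],
                                 b1$plf[match(common, b1$animal)],
                                 paired = TRUE, alpha_norm = st$alpha_norm,
                                 labels = c(sprintf("day%d", dn), sprintf("day%d", d1))),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      dvd[[length(dvd) + 1]] <- data.frame(
        metric = "plf", rate = r, sex = sx, n = length(common),
        delta_mean = mean(a$plf[match(common, a$animal)] -
                            b1$plf[match(common, b1$animal)]),
        test = cmp$test_name, statistic = cmp$statistic, p = cmp$p_value,
        stringsAsFactors = FALSE)
    }
  }
  dvd_df <- if (length(dvd)) do.call(rbind, dvd) else data.frame()

  # baseline sex comparisons, per rate x metric (animal means across days)
  sexcmp <- list()
  if (nrow(base) > 0 &&
      min(table(unique(base[, c("animal", "sex")])$sex)) >= 3) {
    for (r in unique(base$rate)) for (mt in metrics) {
      d <- base[!is.na(base[[mt]]), ]
      cmp <- tryCatch(compare_sexes(d, mt, rate = r, alpha_norm = st$alpha_norm),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      sexcmp[[length(sexcmp) + 1]] <- data.frame(
        metric = mt, rate = r, n_M = cmp$n[1], n_F = cmp$n[2],
        test = cmp$test_name, statistic = cmp$statistic, p = cmp$p_value,
        direction = cmp$effect_direction, stringsAsFactors = FALSE)
    }
    sb <- spont[spont$condition == "baseline", ]
    for (b in bands) {
      cmp <- tryCatch(compare_sexes(sb, b, alpha_norm = st$alpha_norm),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      sexcmp[[length(sexcmp) + 1]] <- data.frame(
        metric = b, rate = NA, n_M = cmp$n[1], n_F = cmp$n[2],
        test = cmp$test_name, statistic = cmp$statistic, p = cmp$p_value,
        direction = cmp$effect_direction, stringsAsFactors = FALSE)
    }
  }
  sex_df <- if (length(sexcmp)) do.call(rbind, sexcmp) else data.frame()

  # ketamine deltas and comparisons
  deltas <- list(); ketcmp <- list()
  drug <- sm[sm$condition %in% c("SAL", "KET"), ]
  if (nrow(drug) > 0 && all(c("SAL", "KET") %in% drug$condition)) {
    sp_drug <- spont[spont$condition %in% c("SAL", "KET"), ]
    for (b in bands) {
      dt <- tryCatch(delta_effect(sp_drug, b), error = function(e) NULL)
      if (is.null(dt)) next
      dt$sex <- sp_drug$sex[match(dt$animal, sp_drug$animal)]
      dt$rate <- NA
      deltas[[length(deltas) + 1]] <- dt
    }
    for (r in unique(drug$rate)) for (mt in metrics) {
      d <- drug[drug$rate == r & !is.na(drug[[mt]]), ]
      dt <- tryCatch(delta_effect(d, mt), error = function(e) NULL)
      if (is.null(dt)) next
      dt$sex <- d$sex[match(dt$animal, d$animal)]
      dt$rate <- r
      deltas[[length(deltas) + 1]] <- dt
    }
    # paired SAL vs KET within each sex, and sex comparison of the deltas
    all_d <- if (length(deltas)) do.call(rbind, deltas) else NULL
    if (!is.null(all_d)) {
      for (key in unique(paste(all_d$metric, all_d$rate))) {
        dsub <- all_d[paste(all_d$metric, all_d$rate) == key, ]
        mt <- dsub$metric[1]; r <- dsub$rate[1]
        src <- if (mt %in% bands) sp_drug else drug[drug$rate %in% r, ]
        for (sx in unique(dsub$sex)) {
          an <- dsub$animal[dsub$sex == sx]
          if (length(an) < 3) next
          ket <- src[[mt]][match(paste(an, "KET"), paste(src$animal, src$condition))]
          sal <- src[[mt]][match(paste(an, "SAL"), paste(src$animal, src$condition))]
          cmp <- tryCatch(route_test(ket, sal, paired = TRUE,
                                     alpha_norm = st$alpha_norm,
                                     labels = c("KET", "SAL")),
                          error = function(e) NULL)
          if (is.null(cmp)) next
          ketcmp[[length(ketcmp) + 1]] <- data.frame(
            metric = mt, rate = r, comparison = "KET vs SAL (paired)", sex = sx,
            n = length(an), test = cmp$test_name, statistic = cmp$statistic,
            p = cmp$p_value, direction = cmp$effect_direction,
            stringsAsFactors = FALSE)
        }
        if (min(table(dsub$sex)) >= 3 && length(unique(dsub$sex)) == 2) {
          cmp <- tryCatch(route_test(dsub$delta[dsub$sex == "M"],
                                     dsub$delta[dsub$sex == "F"],
                                     alpha_norm = st$alpha_norm,
                                     labels = c("M", "F")),
                          error = function(e) NULL)
          if (!is.null(cmp)) {
            ketcmp[[length(ketcmp) + 1]] <- data.frame(
              metric = mt, rate = r, comparison = "delta M vs F (unpaired)",
              sex = "both", n = nrow(dsub), test = cmp$test_name,
              statistic = cmp$statistic, p = cmp$p_value,
              direction = cmp$effect_direction, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  delta_df <- if (length(deltas)) do.call(rbind, deltas) else data.frame()
  ket_df <- if (length(ketcmp)) do.call(rbind, ketcmp) else data.frame()
  fail_df <- if (length(failures)) {
    data.frame(session_id = names(failures), error = unlist(failures),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame()

  report <- structure(
    list(session_metrics = sm, spontaneous = spont, icc = icc_df,
         day_last_vs_first = dvd_df, sex_comparisons = sex_df,
         ket_deltas = delta_df, ket_comparisons = ket_df,
         failures = fail_df, n_failed = length(failures)),
    class = "assr_report"
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    tabs <- list(spontaneous_band_power = spont, assr_metrics = sm,
                 icc_table = icc_df, day_last_vs_first = dvd_df,
                 sex_comparisons = sex_df, ket_deltas = delta_df,
                 ket_comparisons = ket_df, failures = fail_df)
    for (nm in names(tabs)) {
      utils::write.csv(tabs[[nm]], file.path(out, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(out, "run.log"))
    snap <- config
    snap$cohort <- unclass(snap$cohort)
    jsonlite::write_json(unclass(snap), file.path(out, "config_snapshot.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.assr_report <- function(x, ...) {
  cat(sprintf("<assr_report> %d session(s) analyzed, %d failed; %d ICC row(s), %d sex comparison(s), %d ketamine delta row(s)\n",
              nrow(x$session_metrics), x$n_failed, nrow(x$icc),
              nrow(x$sex_comparisons), nrow(x$ket_deltas)))
  invisible(x)
}

#' End-to-end parameter-recovery validation
#'
#' Compares pipeline estimates against the simulation ground truth:
#' estimated PLF vs the closed-form von Mises limit `expected_plf(kappa)` of
#' each session's realized concentration (all sessions, so the drug-induced
#' kappa reduction is exercised), recovered ICC of log band power vs the
#' generative variance-ratio target, and the signs of the group-mean ketamine
#' band-power deltas vs the configured multipliers. Each criterion passes or fails at
#' the configured tolerance. The PLF check is a large-amplitude limit, so it
#' is meaningful only for cohorts whose entrained amplitude dominates the
#' in-band background (see [validation_config()]).
#'
#' @param config A `pipeline_config`.
#' @param cohort An `assr_cohort` carrying ground truth (from
#'   [run_simulate()] or [read_cohort_dir()]).
#' @param tolerances List with `plf` (absolute PLF error) and `icc` (absolute
#'   ICC error); defaults 0.10 and 0.20.
#' @param report Optional precomputed `assr_report` for `cohort` (computed if
#'   missing).
#' @return `data.frame` with columns `criterion`, `value`, `target`,
#'   `tolerance`, `pass`; attribute `"pass"` is the conjunction.
#' @export
run_e2e_validation <- function(config, cohort,
                               tolerances = list(plf = 0.10, icc = 0.20),
                               report = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(cohort$sessions)) stop("empty dataset")
  gt <- cohort$ground_truth
  if (is.null(gt) || is.null(gt$sessions)) stop("ground truth is required for validation")
  if (is.null(report)) report <- run_analyze(config, cohort)
  sm <- report$session_metrics
  rows <- list()

  # 1. PLF vs von Mises closed form, all sessions (drug sessions exercise
  # the kappa reduction)
  kap <- vapply(sm$session_id, function(sid) gt$sessions[[sid]]$kappa, 0)
  err <- mean(abs(sm$plf - expected_plf(kap)))
  rows[[length(rows) + 1]] <- data.frame(
    criterion = "plf_vs_expected_plf", value = err, target = 0,
    tolerance = tolerances$plf, pass = err <= tolerances$plf)

  # 2. ICC of log band power vs variance-ratio target
  sig <- unlist(gt$sigma)
  icc_target <- sig[["animal"]]^2 / sum(sig^2)
  sb <- report$spontaneous[report$spontaneous$condition == "baseline", ]
  if (nrow(sb) > 0 && length(unique(sb$day)) >= 2) {
    sb$logp <- log(sb$beta)
    tb <- icc_table(cbind(sb, all = "all"), "logp", group_col = "all",
                    strict = FALSE)
    err <- abs(tb$ICC[1] - icc_target)
    rows[[length(rows) + 1]] <- data.frame(
      criterion = "icc_vs_variance_ratio", value = err, target = 0,
      tolerance = tolerances$icc, pass = err <= tolerances$icc)
  }

  # 3. spontaneous-band ketamine delta signs vs configured multipliers
  if (nrow(report$ket_deltas) > 0 && !is.null(cohort$spec)) {
    km <- cohort$spec$ket_band_multiplier
    ok <- TRUE
    for (b in names(km)) {
      d <- report$ket_deltas$delta[report$ket_deltas$metric == b]
      if (length(d)) ok <- ok && (sign(mean(d)) == sign(log(km[[b]])))
    }
    rows[[length(rows) + 1]] <- data.frame(
      criterion = "ket_delta_signs", value = as.numeric(ok), target = 1,
      tolerance = 0, pass = ok)
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Small high-signal validation configuration
#'
#' A scaled-down cohort used by the end-to-end validation harness: 10
#' animals per sex, 4 baseline days, the 40 Hz paradigm only, 20 trials per
#' session, and entrained amplitudes large relative to the in-band
#' background so the phase-locking estimate approaches its von Mises limit.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
validation_config <- function(seed = 1) {
  spec <- cohort_spec(
    n_males = 10, n_females = 10, n_days = 4,
    stim_rates_hz = 40, drug_rates_hz = 40, n_trials = 20,
    entrain_amp_uv = list(M = c(`40` = 8), F = c(`40` = 6)),
    kappa = list(M = c(`40` = 1.6), F = c(`40` = 1.2)),
    seed = seed
  )
  pipeline_config(spec, seed = seed)
}
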