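#' Pipeline configuration and end-to-end orchestration
#'
#' One configuration object carries every stage's parameters with
#' defaults matching standard dFNC practice (26-TR tapered window, k = 3
#' city-block states with 5 replicates, minimum support 0.05, 80/20
#' split with 100 x 10-fold evaluation). `run_pipeline()` executes
#' simulate -> windowed FC -> states -> mining -> classification and can
#' persist every intermediate artifact together with a run manifest.
#'
#' @name io_cli
NULL

#' Build a pipeline configuration
#'
#' @param window a `window_spec`
#' @param k number of brain states
#' @param k_range range scanned by the elbow criterion (NULL to skip)
#' @param distance clustering metric
#' @param n_replicates clustering restarts
#' @param mining a `mining_spec`
#' @param protocol a `classification_protocol`
#' @param dichotomy character pair of group labels (A, B)
#' @param synthetic a `synthetic_config` used when no cohort is supplied
#' @param seed master seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(window = window_spec(),
                            k = 3L, k_range = 2:6,
                            distance = "cityblock",
                            n_replicates = 5L,
                            mining = mining_spec(),
                            protocol = classification_protocol(),
                            dichotomy = c("HC", "PD"),
                            synthetic = synthetic_config(),
                            seed = 1L) {
  stopifnot(inherits(window, "window_spec"),
            inherits(mining, "mining_spec"),
            inherits(protocol, "classification_protocol"),
            length(dichotomy) == 2)
  structure(list(window = window, k = as.integer(k), k_range = k_range,
                 distance = distance,
                 n_replicates = as.integer(n_replicates),
                 mining = mining, protocol = protocol,
                 dichotomy = dichotomy, synthetic = synthetic,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field omitted in the file keeps its default; nested sections
#' `window`, `mining`, `protocol` and `synthetic` map onto the
#' corresponding constructors.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  win <- do.call(window_spec, raw$window %||% list())
  mine <- do.call(mining_spec, raw$mining %||% list())
  prot <- do.call(classification_protocol, raw$protocol %||% list())
  syn_args <- raw$synthetic %||% list()
  if (!is.null(syn_args$groups)) {
    syn_args$groups <- lapply(syn_args$groups, function(g) {
      g$transition_matrix <- matrix(unlist(g$transition_matrix),
                                    nrow = length(g$transition_matrix),
                                    byrow = TRUE)
      g
    })
  }
  syn <- do.call(synthetic_config, syn_args)
  pipeline_config(window = win, mining = mine, protocol = prot,
                  synthetic = syn,
                  k = raw$k %||% 3L,
                  k_range = raw$k_range %||% 2:6,
                  distance = raw$distance %||% "cityblock",
                  n_replicates = raw$n_replicates %||% 5L,
                  dichotomy = unlist(raw$dichotomy %||% c("HC", "PD")),
                  seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable content hash of the configuration, for artifact provenance
.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(.jsonable(config), f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

.jsonable <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), .jsonable))
  if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
  x
}

.stage_log <- function(quiet, stage, t0) {
  if (!quiet)
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) synthetic cohort simulation, windowed FC
#' estimation per subject, pooled state clustering (with optional elbow
#' scan), dominant-state sequences and dwell statistics with pairwise
#' group t-tests, per-group sequential pattern mining with the
#' dichotomic partition, and classification from one-hot pattern
#' encodings and from percent dwell times. Deterministic given the
#' configuration seeds.
#'
#' @param config a `pipeline_config`
#' @param cohort optional `dfnc_cohort`; when NULL a synthetic cohort is
#'   simulated from `config$synthetic`
#' @param truth optional `dfnc_ground_truth` for recovery diagnostics
#' @param out_dir optional output directory; when given, every stage's
#'   artifacts are written beneath it
#' @param run_elbow run the elbow scan over `config$k_range`
#' @param quiet suppress per-stage timing messages
#' @return list with cohort, fc, model, sequences, dwell, dwell_tests,
#'   patterns (per group), dpm, features, reports (per feature family),
#'   importance, elbow, config_hash
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         truth = NULL, out_dir = NULL,
                         run_elbow = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- .config_hash(config)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t0 <- as.numeric(Sys.time())
  if (is.null(cohort)) {
    sim <- simulate_cohort(config$synthetic)
    cohort <- sim$cohort
    truth <- sim$truth
    .stage_log(quiet, "simulate", t0)
  }
  groups <- vapply(cohort$subjects, `[[`, "", "group")

  t0 <- as.numeric(Sys.time())
  fc <- lapply(cohort$subjects, function(s)
    estimate_windowed_fc(s$timecourses, config$window,
                         subject_id = s$subject_id,
                         seed = config$seed))
  .stage_log(quiet, "dfnc", t0)

  t0 <- as.numeric(Sys.time())
  pooled <- do.call(rbind, lapply(fc, `[[`, "fc"))
  elbow <- NULL
  if (run_elbow && !is.null(config$k_range))
    elbow <- select_k_elbow(pooled, config$k_range, config$distance,
                            config$n_replicates, config$seed)
  model <- fit_states(pooled, config$k, config$distance,
                      config$n_replicates, config$seed)
  sequences <- lapply(fc, function(w)
    assign_states(model, w, tr_seconds = cohort$subjects[[
      w$subject_id]]$tr_seconds))
  .stage_log(quiet, "states", t0)

  t0 <- as.numeric(Sys.time())
  dwell <- lapply(sequences, dwell_statistics, k = config$k)
  dwell_tests <- rbind(
    dwell_group_comparison(dwell, groups, "fraction_time"),
    dwell_group_comparison(dwell, groups, "mean_dwell_windows"))
  .stage_log(quiet, "dwell", t0)

  t0 <- as.numeric(Sys.time())
  ga <- config$dichotomy[1]; gb <- config$dichotomy[2]
  if (!all(c(ga, gb) %in% groups))
    stop("dichotomy groups not present in cohort: ", ga, " vs ", gb)
  seq_a <- sequences[groups == ga]
  seq_b <- sequences[groups == gb]
  pat_a <- mine_patterns(seq_a, config$mining)
  pat_b <- mine_patterns(seq_b, config$mining)
  dpm <- dichotomic_split(pat_a, pat_b)
  .stage_log(quiet, "mine", t0)

  t0 <- as.numeric(Sys.time())
  sub_ab <- groups %in% c(ga, gb)
  labs <- factor(groups[sub_ab], levels = c(ga, gb))
  seqs_ab <- sequences[sub_ab]
  pat_from_keys <- function(keys)
    lapply(strsplit(keys, "-", fixed = TRUE), as.integer)
  feature_sets <- list()
  if (nrow(dpm$unique_a))
    feature_sets[["unique_a_patterns"]] <-
      one_hot_encode(seqs_ab, pat_from_keys(dpm$unique_a$pattern),
                     compress = config$mining$compress_runs)
  if (nrow(dpm$unique_b))
    feature_sets[["unique_b_patterns"]] <-
      one_hot_encode(seqs_ab, pat_from_keys(dpm$unique_b$pattern),
                     compress = config$mining$compress_runs)
  feature_sets[["percent_dwell_times"]] <- {
    M <- t(vapply(dwell[sub_ab], `[[`, numeric(config$k),
                  "fraction_time"))
    colnames(M) <- paste0("state", seq_len(config$k))
    M
  }
  reports <- lapply(feature_sets, function(Fm)
    evaluate_classifiers(Fm, labs, config$protocol))
  importance <- lapply(reports, rank_feature_importance)
  .stage_log(quiet, "classify", t0)

  result <- list(cohort = cohort, truth = truth, fc = fc,
                 pooled_windows = nrow(pooled),
                 elbow = elbow, model = model, sequences = sequences,
                 dwell = dwell, dwell_tests = dwell_tests,
                 patterns = list(a = pat_a, b = pat_b), dpm = dpm,
                 features = feature_sets, reports = reports,
                 importance = importance, groups = groups,
                 config = config, config_hash = hash)
  if (!is.null(out_dir)) .write_pipeline_artifacts(result, out_dir)
  result
}

.write_pipeline_artifacts <- function(res, out_dir) {
  write_cohort(res$cohort, file.path(out_dir, "cohort"), res$truth)
  fcd <- file.path(out_dir, "fc")
  for (w in res$fc) write_windowed_fc(w, fcd)
  utils::write.csv(res$model$centroids,
                   file.path(out_dir, "state_centroids.csv"),
                   row.names = FALSE)
  seq_long <- do.call(rbind, lapply(res$sequences, function(s)
    data.frame(subject_id = s$subject_id,
               window_index = seq_along(s$labels) - 1L,
               state = s$labels)))
  utils::write.csv(seq_long, file.path(out_dir, "state_sequences.csv"),
                   row.names = FALSE)
  dwell_tab <- do.call(rbind, lapply(names(res$dwell), function(sid) {
    d <- res$dwell[[sid]]
    data.frame(subject_id = sid, state = seq_len(d$k),
               fraction_time = d$fraction_time,
               mean_dwell_windows = d$mean_dwell_windows,
               mean_dwell_seconds = d$mean_dwell_seconds)
  }))
  utils::write.csv(dwell_tab, file.path(out_dir, "dwell_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(res$dwell_tests, file.path(out_dir, "dwell_tests.csv"),
                   row.names = FALSE)
  write_patterns_json(res$patterns$a,
                      file.path(out_dir, "patterns_group_a.json"))
  write_patterns_json(res$patterns$b,
                      file.path(out_dir, "patterns_group_b.json"))
  write_patterns_json(res$dpm, file.path(out_dir, "dpm_result.json"))
  for (nm in names(res$features))
    utils::write.csv(res$features[[nm]],
                     file.path(out_dir, paste0("features_", nm, ".csv")),
                     row.names = FALSE)
  summary <- list(
    config_hash = res$config_hash,
    n_subjects = length(res$cohort$subjects),
    pooled_windows = res$pooled_windows,
    dpm_counts = as.list(res$dpm$counts),
    elbow_k = if (is.null(res$elbow)) NULL else res$elbow$k_star,
    classification = lapply(res$reports, function(r)
      lapply(r$models, function(m)
        list(tuned = as.list(m$tuned), cv_mean = as.list(m$cv_mean),
             cv_sd = as.list(m$cv_sd), holdout = as.list(m$holdout)))),
    importance = res$importance)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
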