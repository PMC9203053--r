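#' Experiment configuration for the end-to-end pipeline
#'
#' Bundles the stimulus range, delay, learning mode and all seeds that the
#' pipeline needs; presets mirror the five study arms (narrower or wider
#' relatedness range crossed with delay, plus a yoked study-only arm).
#'
#' @param preset One of `"narrow_48hr"`, `"narrow_5min"`, `"wide_48hr"`,
#'   `"wide_5min"`, `"study_only"`, `"null"`.
#' @param n_subjects Subjects (multiple of 5).
#' @param n_permutations Permutations for the surface test.
#' @param design_seed,sim_seed,perm_seed Seeds for stimulus construction,
#'   outcome simulation, and the permutation test.
#' @param params Optional [sim_params()] overriding the preset's generator
#'   settings (its `n_subjects`, `delay`, `learning_mode` and `seed` fields
#'   are taken from this config).
#' @param surface A [surface_config()] for the difference surface
#'   (`n_permutations` and `seed` are taken from this config).
#' @return An `experiment_config` list with a reproducibility `manifest`.
#' @export
experiment_config <- function(preset = c("narrow_48hr", "narrow_5min",
                                         "wide_48hr", "wide_5min",
                                         "study_only", "null"),
                              n_subjects = 200, n_permutations = 1000,
                              design_seed = 7L, sim_seed = 11L,
                              perm_seed = 13L, params = NULL,
                              surface = surface_config()) {
  preset <- match.arg(preset)
  narrow <- preset %in% c("narrow_48hr", "narrow_5min", "study_only", "null")
  range <- if (narrow) c(0.03, 0.96) else c(-0.14, 0.95)
  delay <- if (preset %in% c("narrow_5min", "wide_5min")) "5min" else "48hr"
  mode <- if (preset == "study_only") "study" else "retrieval"
  if (is.null(params)) {
    params <- if (preset == "null") preset_params("null")
              else preset_params("paper_stylized")
  }
  params$n_subjects <- n_subjects
  params$delay <- delay
  params$learning_mode <- mode
  params$seed <- as.integer(sim_seed)
  surface$n_permutations <- as.integer(n_permutations)
  surface$seed <- as.integer(perm_seed)
  cfg <- list(preset = preset, range = range, delay = delay,
              learning_mode = mode, n_subjects = n_subjects,
              design_seed = as.integer(design_seed), params = params,
              surface = surface)
  cfg$manifest <- list(
    preset = preset, n_subjects = n_subjects,
    seeds = list(design = cfg$design_seed, simulation = params$seed,
                 permutation = surface$seed),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "manifest")]))
  structure(cfg, class = "experiment_config")
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' simulate -> exclude -> metrics -> inference -> surface. Produces the
#' experiment-level tables a report needs: per-subject condition accuracy
#' with the repeated-measures ANOVA and FDR pairwise tests; item-level
#' regressions of retroactive memorability and dependence on relatedness
#' (target relatedness for the change-target condition, cue relatedness for
#' change-cue, additive cue+target for change-both); dependence tables with
#' mismatched-duo thresholds; the change-both difference surface with
#' cluster permutation; and, in retrieval mode, learning-efficiency
#' correlations and relatedness partial correlations controlling for
#' learning efficiency, plus intrusion-rate correlations.
#'
#' @param config An [experiment_config()].
#' @param verbose Emit per-stage timing and seed messages.
#' @return A `retro_report` list; every table carries the config hash in the
#'   `config_hash` attribute.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  stage <- function(name) {
    if (verbose) {
      message(sprintf("[%s] %+.1fs (seeds d=%d s=%d p=%d)", name,
                      as.numeric(difftime(Sys.time(), t_start, "secs")),
                      config$design_seed, config$params$seed,
                      config$surface$seed))
    }
  }
  stage("design")
  pool <- generate_pair_pool(config$range[1], config$range[2], 90,
                             seed = config$design_seed)
  stimuli <- build_stimulus_grid(
    pool, seed = config$design_seed,
    direction = if (config$range[1] < 0) "undirected" else "backward")
  dataset <- simulate_experiment(config$params, stimuli)
  dataset <- exclude_subjects(
    dataset, drop_zero_base = config$learning_mode == "study")

  stage("metrics")
  subject_scores <- dplyr::summarise(
    dplyr::group_by(dataset$outcomes, .data$subject, .data$condition),
    score = mean(.data$base_correct), .groups = "drop")
  anova <- rm_anova_hf(dplyr::rename(subject_scores, score = "score"))
  pairwise <- pairwise_t_fdr(subject_scores)
  condition_means <- dplyr::summarise(
    dplyr::group_by(subject_scores, .data$condition),
    mean_accuracy = mean(.data$score), sd = sd(.data$score),
    .groups = "drop")

  mem <- memorability(dataset)
  coords <- dplyr::select(as_tibble(stimuli), "id", "r_cue", "r_target")
  mem <- dplyr::left_join(mem, coords, by = c("quartet_id" = "id"))

  reg_x <- list(delta_target = quote(r_target), delta_cue = quote(r_cue),
                delta_both = quote(r_cue + r_target))
  regressions <- purrr::imap(reg_x, function(xq, cond) {
    sub <- mem[mem$condition == cond, ]
    item_regression(x = eval(xq, sub), y = sub$delta_m)
  })

  dep <- purrr::map(names(reg_x), function(cond) {
    tab <- dependence_null(dataset, condition = cond)
    tab <- dplyr::left_join(tab, coords, by = c("quartet_id" = "id"))
    tab
  })
  names(dep) <- names(reg_x)
  dep_regressions <- purrr::imap(reg_x, function(xq, cond) {
    sub <- dep[[cond]]
    item_regression(x = eval(xq, sub), y = sub$d_true)
  })

  stage("surface")
  both <- mem[mem$condition == "delta_both", ]
  ctrl <- mem[mem$condition == "control", ]
  ctrl <- ctrl[match(both$quartet_id, ctrl$quartet_id), ]
  surface <- cluster_permutation(
    tibble(x = both$r_target, y = both$r_cue,
           m_cond = both$m, m_control = ctrl$m),
    config$surface)

  intrusions <- intrusion_rate(dataset)
  intrusions <- dplyr::left_join(intrusions, coords,
                                 by = c("quartet_id" = "id"))
  intrusion_cor <- item_regression(x = intrusions$r_target,
                                   y = intrusions$intrusion_rate)

  learning <- NULL
  if (config$learning_mode == "retrieval") {
    eff <- learning_efficiency(dataset)
    eff <- dplyr::left_join(eff, coords, by = c("quartet_id" = "id"))
    eff_cor <- purrr::imap(reg_x, function(xq, cond) {
      sub <- eff[eff$condition == cond, ]
      item_regression(x = eval(xq, sub), y = sub$mean_trials)
    })
    # relatedness vs memorability partialling out learning efficiency
    partials <- purrr::imap(reg_x, function(xq, cond) {
      sub <- dplyr::inner_join(
        mem[mem$condition == cond, ],
        eff[eff$condition == cond, c("quartet_id", "mean_trials")],
        by = "quartet_id")
      partial_correlation(eval(xq, sub), sub$delta_m, sub$mean_trials)
    })
    learning <- list(efficiency = eff, efficiency_regressions = eff_cor,
                     partial_correlations = partials)
  }

  stage("report")
  report <- list(
    config = config, excluded = dataset$excluded,
    condition_means = condition_means, anova = anova, pairwise = pairwise,
    memorability = mem, regressions = regressions, dependence = dep,
    dependence_regressions = dep_regressions, surface = surface,
    intrusions = intrusions, intrusion_regression = intrusion_cor,
    learning = learning)
  report <- tag_hash(report, config$manifest$config_hash)
  structure(report, class = "retro_report")
}

tag_hash <- function(x, hash) {
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) attr(x[[nm]], "config_hash") <- hash
  }
  attr(x, "config_hash") <- hash
  x
}

#' @export
print.retro_report <- function(x, ...) {
  cat(sprintf("<retro_report: preset %s, %d subjects, hash %s>\n",
              x$config$preset, x$config$n_subjects,
              substr(attr(x, "config_hash"), 1, 8)))
  print(x$anova)
  print(x$condition_means)
  invisible(x)
}

#' Machine-readable summary of a pipeline report
#'
#' @param report A `retro_report`.
#' @param path Optional path; when given, the summary is written as JSON.
#' @return The summary list (invisibly when writing).
#' @export
report_summary <- function(report, path = NULL) {
  reg_row <- function(r) list(slope = r$slope, slope_p = r$slope_p,
                              intercept = r$intercept,
                              intercept_p = r$intercept_p, r = r$r)
  out <- list(
    preset = report$config$preset,
    config_hash = attr(report, "config_hash"),
    n_excluded = length(report$excluded),
    condition_means = report$condition_means,
    anova = as.list(tidy(report$anova)[1, ]),
    memorability_regressions = purrr::map(report$regressions, reg_row),
    dependence_regressions = purrr::map(report$dependence_regressions,
                                        reg_row),
    dependence_mean_thresholds = purrr::map(
      report$dependence, ~ attr(.x, "mean_threshold")),
    clusters = report$surface$clusters,
    intrusion_regression = reg_row(report$intrusion_regression))
  if (!is.null(report$learning)) {
    out$learning_regressions <- purrr::map(
      report$learning$efficiency_regressions, reg_row)
    out$partial_correlations <- purrr::map(
      report$learning$partial_correlations, ~ as.list(.x[1, ]))
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    return(invisible(out))
  }
  out
}

#' Map an external trial-outcome export onto the internal outcome dialect
#'
#' Adapter for user-supplied deposits: renames columns according to a
#' mapping (given directly or as a YAML file with a top-level `columns`
#' block), recodes condition labels, and returns an outcomes tibble usable
#' by the metric functions. Nothing is downloaded.
#'
#' @param path CSV file with one row per (subject, pair) final-test record.
#' @param mapping Named list/character vector mapping internal column names
#'   (`subject`, `quartet_id`, `condition`, `base_correct`,
#'   `secondary_correct`, `base_response`, `trials_to_criterion`) to the
#'   export's column names, or a path to a YAML file with `columns:` and
#'   optional `conditions:` (internal label -> export label) blocks.
#' @return An outcomes tibble.
#' @export
read_outcome_export <- function(path, mapping) {
  cond_map <- NULL
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    y <- yaml::read_yaml(mapping)
    cond_map <- y$conditions
    mapping <- y$columns
  }
  mapping <- unlist(mapping)
  required <- c("subject", "quartet_id", "condition", "base_correct")
  if (!all(required %in% names(mapping))) {
    abort(sprintf("Mapping must cover at least: %s.",
                  paste(required, collapse = ", ")))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Export lacks mapped column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(.rows = nrow(raw))
  for (nm in names(mapping)) out[[nm]] <- raw[[mapping[[nm]]]]
  if (!is.null(cond_map)) {
    rev_map <- setNames(names(cond_map), unlist(cond_map))
    out$condition <- unname(rev_map[as.character(out$condition)])
  }
  bad <- setdiff(unique(out$condition), retro_conditions())
  if (length(bad) > 0) {
    abort(sprintf("Unmapped condition label(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  for (nm in c("secondary_correct", "base_response",
               "trials_to_criterion")) {
    if (!nm %in% names(out)) {
      out[[nm]] <- if (nm == "base_response") NA_character_ else NA_integer_
    }
  }
  out
}
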