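#' Exclude low-performing subjects
#'
#' Removes subjects whose overall accuracy (base and secondary final tests
#' pooled) falls more than `sd_cutoff` standard deviations below the
#' across-subject mean. With zero variance no one is excluded. The optional
#' study-only rule additionally drops subjects with no correct base-pair
#' responses even when they fall inside the cutoff.
#'
#' @param dataset A `retro_dataset` (or a plain outcomes tibble).
#' @param sd_cutoff Standard-deviation multiplier (default 4).
#' @param drop_zero_base Apply the study-only zero-correct rule.
#' @return For a `retro_dataset`, the dataset with excluded subjects removed
#'   and their ids recorded in `$excluded`; for a tibble, a list with
#'   `outcomes` and `excluded`.
#' @export
exclude_subjects <- function(dataset, sd_cutoff = 4, drop_zero_base = FALSE) {
  outcomes <- if (inherits(dataset, "retro_dataset")) dataset$outcomes
              else as_tibble(dataset)
  if (length(unique(outcomes$subject)) < 2) {
    abort("At least two subjects are required.")
  }
  per <- dplyr::summarise(
    dplyr::group_by(outcomes, .data$subject),
    accuracy = mean(c(.data$base_correct, .data$secondary_correct),
                    na.rm = TRUE),
    base_any = sum(.data$base_correct) > 0,
    .groups = "drop")
  mu <- mean(per$accuracy)
  sdev <- sd(per$accuracy)
  low <- if (is.na(sdev) || sdev == 0) rep(FALSE, nrow(per))
         else per$accuracy < mu - sd_cutoff * sdev
  zero <- if (drop_zero_base) !per$base_any else rep(FALSE, nrow(per))
  excluded <- sort(per$subject[low | zero])
  outcomes <- outcomes[!outcomes$subject %in% excluded, ]
  if (inherits(dataset, "retro_dataset")) {
    dataset$outcomes <- outcomes
    dataset$plan <- dataset$plan[!dataset$plan$subject %in% excluded, ]
    dataset$excluded <- excluded
    dataset
  } else {
    list(outcomes = outcomes, excluded = excluded)
  }
}

as_outcomes <- function(x) {
  if (inherits(x, "retro_dataset")) x$outcomes else as_tibble(x)
}

#' Across-subject memorability per pair and condition
#'
#' Memorability `M` is the proportion of subjects who recalled a base pair
#' in a given condition; the retroactive effect `delta_m` is `M` in a shown
#' condition minus `M` for the same pair in the unshown control.
#'
#' @param data A `retro_dataset` or outcomes tibble (columns `subject`,
#'   `quartet_id`, `condition`, `base_correct`).
#' @return A `memorability_table` tibble: `quartet_id`, `condition`, `n`,
#'   `m`, `delta_m` (`NA` for control rows).
#' @export
memorability <- function(data) {
  outcomes <- as_outcomes(data)
  tab <- dplyr::summarise(
    dplyr::group_by(outcomes, .data$quartet_id, .data$condition),
    n = dplyr::n(), m = mean(.data$base_correct), .groups = "drop")
  full <- tidyr::expand_grid(quartet_id = unique(outcomes$quartet_id),
                             condition = retro_conditions())
  gaps <- dplyr::anti_join(full, tab, by = c("quartet_id", "condition"))
  if (nrow(gaps) > 0) {
    abort(sprintf(
      "No observations for (pair %s, condition %s)%s.",
      gaps$quartet_id[1], gaps$condition[1],
      if (nrow(gaps) > 1) sprintf(" and %d more cells", nrow(gaps) - 1)
      else ""))
  }
  ctrl <- dplyr::select(
    dplyr::filter(tab, .data$condition == "control"),
    "quartet_id", m_control = "m")
  tab <- dplyr::left_join(tab, ctrl, by = "quartet_id")
  tab$delta_m <- ifelse(tab$condition == "control", NA_real_,
                        tab$m - tab$m_control)
  tab$m_control <- NULL
  class(tab) <- c("memorability_table", class(tab))
  tab
}

#' Across-subject dependence of two outcome vectors
#'
#' The proportion of aligned subjects for whom both outcomes agree (both
#' correct or both incorrect); equivalently `1 - hamming / n`.
#'
#' @param base,secondary Equal-length binary vectors aligned on subjects.
#' @return Scalar in `[0, 1]`.
#' @examples
#' dependence(c(1, 1, 1, 0), c(1, 1, 0, 0))  # 0.75
#' dependence(c(1, 1, 1, 0), c(0, 1, 0, 1))  # 0.25
#' @export
dependence <- function(base, secondary) {
  if (length(base) != length(secondary)) {
    abort("`base` and `secondary` must have equal length.")
  }
  if (length(base) < 1) abort("At least one aligned subject is required.")
  stopifnot(all(base %in% 0:1), all(secondary %in% 0:1))
  mean(base == secondary)
}

# Per-pair outcome vectors within one condition, ordered by subject id.
condition_vectors <- function(outcomes, cond) {
  sub <- outcomes[outcomes$condition == cond &
                    !is.na(outcomes$secondary_correct), ]
  sub <- dplyr::arrange(sub, .data$quartet_id, .data$subject)
  split(sub[c("subject", "base_correct", "secondary_correct")],
        sub$quartet_id)
}

#' Per-duo dependence with mismatched-pair null thresholds
#'
#' For every pair in a shown condition, computes the dependence of its base
#' outcomes with its own secondary outcomes (the true duo) and with the
#' secondary outcomes of each of the other pairs in the same condition
#' (mismatched duos). Pairs held by different subject subsets are aligned by
#' subject order and truncated to the common length. The exceedance
#' criterion asks whether the true dependence exceeds all but one mismatched
#' value, i.e. a fraction `(n_pairs - 2) / (n_pairs - 1)` of them
#' (43/44 = 0.977 for a 45-pair set); the per-pair threshold is the
#' second-largest mismatched value, and their mean is the per-experiment
#' threshold line.
#'
#' @param data A `retro_dataset` or outcomes tibble.
#' @param condition A shown condition (default `"delta_target"`).
#' @return A `dependence_table` tibble with columns `quartet_id`, `n`,
#'   `d_true`, `n_null`, `criterion_fraction`, `threshold`, `exceeded`
#'   (fraction of mismatched values strictly below `d_true`), `pass`; the
#'   full null values sit in the `null` list-column, and the mean threshold
#'   is in the `mean_threshold` attribute.
#' @export
dependence_null <- function(data, condition = "delta_target") {
  outcomes <- as_outcomes(data)
  vecs <- condition_vectors(outcomes, condition)
  n_pairs <- length(vecs)
  if (n_pairs < 3) abort("At least 3 pairs are required for the null.")
  ids <- names(vecs)
  crit <- (n_pairs - 2) / (n_pairs - 1)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    b <- vecs[[i]]$base_correct
    d_true <- dependence(b, vecs[[i]]$secondary_correct)
    null_vals <- vapply(seq_len(n_pairs)[-i], function(j) {
      s <- vecs[[j]]$secondary_correct
      k <- min(length(b), length(s))
      dependence(b[seq_len(k)], s[seq_len(k)])
    }, numeric(1))
    thr <- sort(null_vals, decreasing = TRUE)[2]
    exceeded <- mean(null_vals < d_true)
    rows[[i]] <- tibble(
      quartet_id = as.integer(ids[i]), n = length(b), d_true = d_true,
      n_null = n_pairs - 1L, criterion_fraction = crit, threshold = thr,
      exceeded = exceeded, pass = exceeded >= crit, null = list(null_vals))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_threshold") <- mean(out$threshold)
  class(out) <- c("dependence_table", class(out))
  out
}

#' Per-pair dependence within a condition
#'
#' True-duo dependence values only (no null), convenient for regressions and
#' surfaces.
#'
#' @inheritParams dependence_null
#' @return Tibble with `quartet_id`, `n`, `d`.
#' @export
dependence_table <- function(data, condition = "delta_target") {
  vecs <- condition_vectors(as_outcomes(data), condition)
  dplyr::bind_rows(purrr::imap(vecs, function(v, id) {
    tibble(quartet_id = as.integer(id), n = nrow(v),
           d = dependence(v$base_correct, v$secondary_correct))
  }))
}

#' Across-subject intrusion rates
#'
#' For each pair in the `delta_target` condition, the proportion of subjects
#' whose base-test response string equals the secondary-list target
#' (case-folded, whitespace-trimmed). Missing responses never match.
#'
#' @param data A `retro_dataset`, or an outcomes tibble plus `stimuli`.
#' @param stimuli Stimulus set (only needed when `data` is a tibble).
#' @param fuzzy_match Also count responses within edit distance 1 of the
#'   secondary target (off by default: the scoring rule is exact match
#'   after case-folding and trimming).
#' @return Tibble with `quartet_id`, `n`, `intrusion_rate`.
#' @export
intrusion_rate <- function(data, stimuli = NULL, fuzzy_match = FALSE) {
  outcomes <- as_outcomes(data)
  if (is.null(stimuli) && inherits(data, "retro_dataset")) {
    stimuli <- data$stimuli
  }
  if (is.null(stimuli)) abort("`stimuli` is required.")
  sub <- outcomes[outcomes$condition == "delta_target", ]
  sub <- dplyr::left_join(
    sub, dplyr::select(as_tibble(stimuli), "id", "delta_target"),
    by = c("quartet_id" = "id"))
  resp <- fold_word(sub$base_response)
  tgt <- fold_word(sub$delta_target)
  sub$intruded <- if (fuzzy_match) {
    dist <- mapply(function(a, b) {
      if (is.na(a)) NA_integer_ else utils::adist(a, b)[1, 1]
    }, resp, tgt)
    !is.na(dist) & dist <= 1
  } else {
    !is.na(resp) & resp == tgt
  }
  dplyr::summarise(dplyr::group_by(sub, .data$quartet_id),
                   n = dplyr::n(), intrusion_rate = mean(.data$intruded),
                   .groups = "drop")
}

#' Per-pair learning efficiency
#'
#' Mean trials to criterion (retrieval attempts until first success) across
#' subjects, per pair and condition. Only defined for retrieval-to-criterion
#' learning; a study-only dataset has no learning measure.
#'
#' @param data A `retro_dataset`.
#' @return Tibble with `quartet_id`, `condition`, `n`, `mean_trials`.
#' @export
learning_efficiency <- function(data) {
  if (inherits(data, "retro_dataset") &&
      data$params$learning_mode != "retrieval") {
    abort("The study-only experiment has no learning measure.")
  }
  outcomes <- as_outcomes(data)
  sub <- outcomes[!is.na(outcomes$trials_to_criterion), ]
  if (nrow(sub) == 0) {
    abort("The study-only experiment has no learning measure.")
  }
  dplyr::summarise(
    dplyr::group_by(sub, .data$quartet_id, .data$condition),
    n = dplyr::n(), mean_trials = mean(.data$trials_to_criterion),
    .groups = "drop")
}
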