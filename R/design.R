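#' Build the 45-quartet stimulus grid from 90 relation pairs
#'
#' Implements the two-stage stimulus construction of the counterbalanced
#' two-list design. The 90 input pairs are split into relatedness terciles of
#' 30; within each tercile, 15 pairs become cue units (cue, delta-cue) and 15
#' target units (target, delta-target); each tercile's 15 cue units are
#' spread 5/5/5 over the three target terciles (and vice versa), yielding a
#' 3x3 grid of cells with 5 cue and 5 target units each; within each cell the
#' units are randomly matched into 5 quartets. Ties at tercile boundaries are
#' broken by a stable sort on (relatedness, first word), so the construction
#' is reproducible from (input, seed).
#'
#' @param pairs Data frame with columns `word_a`, `word_b`, `relatedness`
#'   (exactly 90 rows; all 180 words distinct). `word_a` is the word that
#'   enters the base list (cue or target), `word_b` its secondary-list
#'   counterpart (delta-cue or delta-target).
#' @param seed Integer seed controlling all randomization.
#' @param direction Annotation describing how relatedness was measured:
#'   `"backward"` for directed association norms designed secondary -> base,
#'   `"undirected"` for symmetric metrics such as embedding cosines.
#' @return A `stimulus_set` tibble with 45 rows and columns `id`, `cue`,
#'   `delta_cue`, `target`, `delta_target`, `r_cue`, `r_target`, `cell`
#'   (e.g. `"l/h"`, cue tercile / target tercile), `slot` (1-5 within cell)
#'   and `direction`.
#' @export
build_stimulus_grid <- function(pairs, seed = 1L,
                                direction = c("backward", "undirected")) {
  direction <- match.arg(direction)
  pairs <- as_tibble(pairs)
  stopifnot(all(c("word_a", "word_b", "relatedness") %in% names(pairs)))
  if (nrow(pairs) != 90) abort("Exactly 90 relation pairs are required.")
  if (any(!is.finite(pairs$relatedness))) {
    abort("All relatedness values must be finite.")
  }
  words <- c(fold_word(pairs$word_a), fold_word(pairs$word_b))
  if (anyDuplicated(words)) {
    abort("All 180 words across the 90 pairs must be distinct.")
  }
  withr::local_seed(seed)
  levels3 <- c("l", "m", "h")
  ord <- order(pairs$relatedness, fold_word(pairs$word_a), method = "radix")
  pairs <- pairs[ord, ]
  pairs$tercile <- rep(levels3, each = 30)

  assigned <- vector("list", 3)
  for (ti in 1:3) {
    block <- pairs[pairs$tercile == levels3[ti], ]
    shuffle <- block[sample.int(30), ]
    cue_units <- shuffle[1:15, ]
    target_units <- shuffle[16:30, ]
    # 5/5/5 allocation of this tercile's units across the opposite axis
    cue_units$other_tercile <- sample(rep(levels3, each = 5))
    target_units$other_tercile <- sample(rep(levels3, each = 5))
    cue_units$role <- "cue"
    target_units$role <- "target"
    assigned[[ti]] <- dplyr::bind_rows(cue_units, target_units)
  }
  units <- dplyr::bind_rows(assigned)

  quartets <- vector("list", 9)
  qi <- 0
  for (ci in levels3) {
    for (tj in levels3) {
      cu <- units[units$role == "cue" & units$tercile == ci &
                    units$other_tercile == tj, ]
      tu <- units[units$role == "target" & units$tercile == tj &
                    units$other_tercile == ci, ]
      stopifnot(nrow(cu) == 5, nrow(tu) == 5)
      tu <- tu[sample.int(5), ]
      qi <- qi + 1
      quartets[[qi]] <- tibble(
        cue = fold_word(cu$word_a), delta_cue = fold_word(cu$word_b),
        target = fold_word(tu$word_a), delta_target = fold_word(tu$word_b),
        r_cue = cu$relatedness, r_target = tu$relatedness,
        cell = paste(ci, tj, sep = "/"), slot = 1:5)
    }
  }
  out <- dplyr::bind_rows(quartets)
  out <- dplyr::mutate(out, id = dplyr::row_number(), direction = direction,
                       .before = 1)
  class(out) <- c("stimulus_set", class(out))
  out
}

#' Counterbalance quartets over subjects
#'
#' Rotates the five secondary-list conditions over the five quartet slots of
#' each grid cell, advancing by one every subject, so that within any block
#' of five consecutive subjects each quartet serves in every condition
#' exactly once and every subject holds 9 quartets (one per cell) in each
#' condition.
#'
#' @param stimuli A [build_stimulus_grid()] stimulus set.
#' @param n_subjects Number of subjects; must be a multiple of 5.
#' @return A `counterbalance_plan` tibble with columns `subject`,
#'   `quartet_id`, `condition`.
#' @export
counterbalance <- function(stimuli, n_subjects) {
  if (n_subjects < 5 || n_subjects %% 5 != 0) {
    abort("`n_subjects` must be a positive multiple of 5.")
  }
  conds <- retro_conditions()
  base <- tibble(quartet_id = stimuli$id, slot = stimuli$slot)
  plan <- tidyr::expand_grid(subject = seq_len(n_subjects), base)
  plan$condition <- conds[((plan$slot - 1L + (plan$subject - 1L)) %% 5L) + 1L]
  plan <- dplyr::select(plan, "subject", "quartet_id", "condition")
  class(plan) <- c("counterbalance_plan", class(plan))
  plan
}

#' Secondary-list item shown for a quartet under a condition
#'
#' `no_delta` re-presents the base pair; `delta_target` pairs the original
#' cue with the delta-target; `delta_cue` pairs the delta-cue with the
#' original target; `delta_both` pairs the two delta words; `control` shows
#' nothing in the secondary phase.
#'
#' @param stimuli A stimulus set (any rows).
#' @param condition Character vector, recycled against the rows of `stimuli`.
#' @return Tibble with `quartet_id`, `condition`, `sec_cue`, `sec_target`
#'   (`NA` for control).
#' @export
secondary_item <- function(stimuli, condition) {
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), retro_conditions())
  if (length(bad) > 0) {
    abort(sprintf("Unknown condition(s): %s.", paste(bad, collapse = ", ")))
  }
  n <- nrow(stimuli)
  condition <- rep_len(condition, n)
  sec_cue <- dplyr::case_when(
    condition %in% c("no_delta", "delta_target") ~ stimuli$cue,
    condition %in% c("delta_cue", "delta_both") ~ stimuli$delta_cue,
    TRUE ~ NA_character_)
  sec_target <- dplyr::case_when(
    condition %in% c("no_delta", "delta_cue") ~ stimuli$target,
    condition %in% c("delta_target", "delta_both") ~ stimuli$delta_target,
    TRUE ~ NA_character_)
  tibble(quartet_id = stimuli$id, condition = condition,
         sec_cue = sec_cue, sec_target = sec_target)
}

#' Expand per-pair trials-to-criterion into a retrieval learning schedule
#'
#' In retrieval-to-criterion learning every pair is encoded once and then
#' retrieved on successive rounds until first correct; correct pairs drop out
#' of later rounds. A pair with `trials_to_criterion = t` therefore appears
#' in retrieval rounds `1..t` and is marked correct in round `t`. Order
#' within each round is randomized under `seed`.
#'
#' @param trials Data frame with columns `subject`, `pair_id`,
#'   `trials_to_criterion` (positive integers), and optionally `phase`.
#' @param seed Integer seed for within-round ordering.
#' @return A `learning_schedule` tibble: `subject`, `phase`, `round`
#'   (0 = encoding), `order`, `pair_id`, `trial_type`, `correct`.
#' @export
build_learning_schedule <- function(trials, seed = 1L) {
  trials <- as_tibble(trials)
  stopifnot(all(c("subject", "pair_id", "trials_to_criterion") %in%
                  names(trials)))
  if (!"phase" %in% names(trials)) trials$phase <- "secondary"
  if (any(trials$trials_to_criterion < 1 |
            trials$trials_to_criterion != round(trials$trials_to_criterion))) {
    abort("`trials_to_criterion` must be positive integers.")
  }
  withr::local_seed(seed)
  per_round <- tidyr::uncount(trials, weights = .data$trials_to_criterion,
                              .id = "round", .remove = FALSE)
  per_round$trial_type <- "retrieve"
  per_round$correct <- per_round$round == per_round$trials_to_criterion
  encode <- dplyr::distinct(trials, .data$subject, .data$phase, .data$pair_id)
  encode$round <- 0L
  encode$trial_type <- "encode"
  encode$correct <- NA
  sched <- dplyr::bind_rows(
    encode, per_round[c("subject", "phase", "pair_id", "round",
                        "trial_type", "correct")])
  sched <- dplyr::group_by(sched, .data$subject, .data$phase, .data$round)
  sched <- dplyr::mutate(sched, order = sample.int(dplyr::n()))
  sched <- dplyr::ungroup(sched)
  sched <- dplyr::arrange(sched, .data$subject, .data$phase, .data$round,
                          .data$order)
  sched <- dplyr::select(sched, "subject", "phase", "round", "order",
                         "pair_id", "trial_type", "correct")
  class(sched) <- c("learning_schedule", class(sched))
  sched
}

#' Yoke a study-only schedule to a retrieval-to-criterion donor
#'
#' Copies a donor subject's learning order and dropout exactly: the yoked
#' subject restudies each pair in the same rounds and positions in which the
#' donor encoded or retrieved it, with retrieval replaced by restudy. The
#' donor must be complete (every pair correct on its final appearance).
#'
#' @param donor_schedule A [build_learning_schedule()] schedule.
#' @return A `learning_schedule` with `trial_type` `"restudy"` for all
#'   former retrieval trials (encoding trials are kept as encoding).
#' @export
yoke <- function(donor_schedule) {
  sched <- as_tibble(donor_schedule)
  ret <- sched[sched$trial_type == "retrieve", ]
  last <- dplyr::slice_max(
    dplyr::group_by(ret, .data$subject, .data$phase, .data$pair_id),
    .data$round, n = 1, with_ties = FALSE)
  if (!all(last$correct)) {
    abort("Donor schedule is incomplete: some pairs never reached criterion.")
  }
  sched$trial_type[sched$trial_type == "retrieve"] <- "restudy"
  sched$correct <- NA
  class(sched) <- c("learning_schedule", class(sched))
  sched
}
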