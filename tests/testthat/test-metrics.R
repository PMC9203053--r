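# Exclusions, memorability, dependence (with mismatched-duo nulls),
# intrusions, and learning efficiency.

test_that("dependence reproduces the worked examples and its Hamming
           identity", {
  expect_equal(dependence(c(1, 1, 1, 0), c(1, 1, 0, 0)), 0.75)
  expect_equal(dependence(c(1, 1, 1, 0), c(0, 1, 0, 1)), 0.25)
  expect_equal(dependence(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_error(dependence(c(1, 0), c(1, 0, 1)), "equal length")
  # independent check: 1 - normalized Hamming distance
  withr::local_seed(5)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    expect_equal(dependence(a, b), 1 - sum(a != b) / n)
    expect_true(dependence(a, b) >= 0 && dependence(a, b) <= 1)
  }
})

test_that("memorability computes per-cell proportions and control
           differences", {
  # the 3/4 vs 2/4 worked example
  out <- tibble::tibble(
    subject = c(2, 7, 12, 17, 5, 10, 15, 20),
    quartet_id = 1L,
    condition = rep(c("delta_target", "control"), each = 4),
    base_correct = c(1, 1, 1, 0, 1, 1, 0, 0))
  # complete the remaining cells so the grid has no gaps
  filler <- tidyr::expand_grid(
    subject = 99:102,
    condition = c("no_delta", "delta_cue", "delta_both"))
  filler$quartet_id <- 1L
  filler$base_correct <- 1
  tab <- memorability(dplyr::bind_rows(out, filler))
  expect_equal(tab$m[tab$condition == "delta_target"], 0.75)
  expect_equal(tab$m[tab$condition == "control"], 0.5)
  expect_equal(tab$delta_m[tab$condition == "delta_target"], 0.25)
  expect_true(is.na(tab$delta_m[tab$condition == "control"]))
  # identical outcomes give a zero difference
  same <- out
  same$base_correct <- rep(c(1, 1, 0, 0), 2)
  tab2 <- memorability(dplyr::bind_rows(same, filler))
  expect_equal(tab2$delta_m[tab2$condition == "delta_target"], 0)
  # empty cell is a named error
  expect_error(memorability(out), "no_delta")
})

test_that("memorability conserves totals and matches overall condition
           accuracy", {
  ds <- small_dataset(n_subjects = 15, seed = 61)
  tab <- memorability(ds)
  expect_equal(sum(tab$m * tab$n), sum(ds$outcomes$base_correct))
  overall <- dplyr::summarise(
    dplyr::group_by(ds$outcomes, condition),
    acc = mean(base_correct), .groups = "drop")
  weighted <- dplyr::summarise(
    dplyr::group_by(tab, condition),
    acc = sum(m * n) / sum(n), .groups = "drop")
  expect_equal(dplyr::arrange(weighted, condition),
               dplyr::arrange(overall, condition))
})

test_that("subject exclusion applies the 4-SD rule and the study-only
           zero-correct flag", {
  ds <- small_dataset(n_subjects = 200, seed = 71)
  # uniform accuracy: nobody excluded under zero-variance convention
  flat <- ds$outcomes
  flat$base_correct <- 1L
  flat$secondary_correct <- ifelse(is.na(flat$secondary_correct), NA, 1L)
  expect_length(exclude_subjects(flat)$excluded, 0)

  # plant one catastrophic subject; direct mean - 4 SD recomputation
  out <- ds$outcomes
  out$base_correct[out$subject == 7] <- 0L
  out$secondary_correct[out$subject == 7 &
                          !is.na(out$secondary_correct)] <- 0L
  acc <- dplyr::summarise(
    dplyr::group_by(out, subject),
    a = mean(c(base_correct, secondary_correct), na.rm = TRUE),
    .groups = "drop")
  expected <- acc$subject[acc$a < mean(acc$a) - 4 * sd(acc$a)]
  got <- exclude_subjects(out)
  expect_equal(got$excluded, sort(expected))
  expect_true(7 %in% got$excluded)

  # a zero-correct-base subject inside 4 SD is dropped only under the flag
  out2 <- ds$outcomes
  out2$base_correct[out2$subject == 9] <- 0L
  excl_default <- exclude_subjects(out2)$excluded
  excl_flag <- exclude_subjects(out2, drop_zero_base = TRUE)$excluded
  if (!9 %in% excl_default) {
    expect_true(9 %in% excl_flag)
  }
  expect_true(all(excl_default %in% excl_flag))
})

test_that("the mismatched-duo criterion is 43/44 for a 45-pair set and
           passes obvious cases", {
  ds <- small_dataset(n_subjects = 20, seed = 81)
  tab <- dependence_null(ds, "delta_target")
  expect_equal(nrow(tab), 45)
  expect_equal(tab$n_null, rep(44L, 45))
  expect_equal(unique(tab$criterion_fraction), 43 / 44)
  expect_equal(round(unique(tab$criterion_fraction), 3), 0.977)
  expect_true(all(lengths(tab$null) == 44))
  expect_false(is.null(attr(tab, "mean_threshold")))

  # perfect true duo with imperfect mismatches must pass
  out <- tidyr::expand_grid(subject = 1:8, quartet_id = 1:5)
  out$condition <- "delta_target"
  withr::local_seed(3)
  out$secondary_correct <- rbinom(nrow(out), 1, 0.5)
  out$base_correct <- ifelse(out$quartet_id == 1, out$secondary_correct,
                             rbinom(nrow(out), 1, 0.5))
  tab2 <- dependence_null(out, "delta_target")
  expect_equal(tab2$d_true[tab2$quartet_id == 1], 1)
  expect_true(tab2$pass[tab2$quartet_id == 1])
  expect_error(dependence_null(out[out$quartet_id <= 2, ]), "At least 3")
})

test_that("under shuffled null outcomes the criterion pass rate matches its
           rank-based tail probability", {
  # Exchangeable duos: the true duo ranks uniformly among the 45 dependence
  # values, so P(pass) = P(rank above all but at most one of 44) = 2/45.
  withr::local_seed(91)
  n_pairs <- 45
  passes <- 0
  n_datasets <- 12  # 540 pair-level trials in total
  for (r in seq_len(n_datasets)) {
    out <- tidyr::expand_grid(subject = 1:40,
                              quartet_id = seq_len(n_pairs))
    out$condition <- "delta_target"
    out$base_correct <- rbinom(nrow(out), 1, 0.5)
    out$secondary_correct <- rbinom(nrow(out), 1, 0.5)
    tab <- dependence_null(out, "delta_target")
    passes <- passes + sum(tab$pass)
  }
  rate <- passes / (n_datasets * n_pairs)
  expected <- 2 / 45
  ci_half <- 1.96 * sqrt(expected * (1 - expected) /
                           (n_datasets * n_pairs))
  # ties make the test slightly conservative; allow the CI plus tie slack
  expect_lt(abs(rate - expected), ci_half + 0.02)
})

test_that("memorability and dependence are dissociable between floor and
           ceiling", {
  # high memorability, low dependence: both lists near 50% but mismatched
  base <- c(1, 0, 1, 0, 1, 0, 1, 0)
  secondary <- 1 - base
  expect_equal(mean(base), 0.5)
  expect_equal(dependence(base, secondary), 0)
  # low memorability, high dependence: jointly forgotten
  base2 <- c(0, 0, 0, 0, 0, 0, 1, 0)
  expect_lt(mean(base2), 0.2)
  expect_equal(dependence(base2, base2), 1)
})

test_that("intrusion rates count matching secondary-target responses", {
  ds <- small_dataset(n_subjects = 10, seed = 101)
  tab <- intrusion_rate(ds)
  expect_equal(nrow(tab), 45)
  expect_true(all(tab$intrusion_rate >= 0 & tab$intrusion_rate <= 1))

  # counting example: 2 of 40 subjects intrude -> 0.05
  stim <- ds$stimuli[1, ]
  out <- tibble::tibble(
    subject = 1:40, quartet_id = stim$id, condition = "delta_target",
    base_correct = 0L,
    base_response = c(rep(stim$delta_target, 2), rep(NA, 38)))
  expect_equal(intrusion_rate(out, stimuli = ds$stimuli)$intrusion_rate[1],
               0.05)
  none <- out
  none$base_response <- NA
  expect_equal(intrusion_rate(none, stimuli = ds$stimuli)$intrusion_rate[1],
               0)
})

test_that("simulated intrusion rates match the analytic expectation", {
  ds <- small_dataset(n_subjects = 600, seed = 111, preset = "null",
                      iota = 0.2)
  out <- ds$outcomes[ds$outcomes$condition == "delta_target", ]
  p_fail <- mean(out$base_correct == 0)
  tab <- intrusion_rate(ds)
  observed <- sum(tab$intrusion_rate * tab$n) / sum(tab$n)
  expect_lt(abs(observed - 0.2 * p_fail), 0.02)
})

test_that("learning efficiency averages trials to criterion and matches the
           geometric closed form", {
  ds <- small_dataset(n_subjects = 500, seed = 121, preset = "null",
                      lambda0 = 0, lambda1 = 0)
  eff <- learning_efficiency(ds)
  # all-shown conditions present, control absent
  expect_setequal(unique(eff$condition),
                  c("no_delta", "delta_target", "delta_cue", "delta_both"))
  # lambda0 = 0, lambda1 = 0: success probability 0.5, mean trials 1/p = 2
  expect_lt(abs(mean(eff$mean_trials) - 2), 0.05)

  # all-correct-first-try datasets give exactly 1
  one <- ds$outcomes
  one$trials_to_criterion[!is.na(one$trials_to_criterion)] <- 1L
  ds_one <- ds; ds_one$outcomes <- one
  expect_true(all(learning_efficiency(ds_one)$mean_trials == 1))

  # study-only data have no learning measure
  ds_study <- small_dataset(n_subjects = 10, seed = 6,
                            learning_mode = "study")
  expect_error(learning_efficiency(ds_study), "no learning measure")
})

test_that("under the stylized preset no-delta pairs are learned fastest", {
  ds <- small_dataset(n_subjects = 100, seed = 131)
  eff <- dplyr::summarise(
    dplyr::group_by(learning_efficiency(ds), condition),
    m = mean(mean_trials), .groups = "drop")
  m_no <- eff$m[eff$condition == "no_delta"]
  expect_true(all(m_no <= eff$m[eff$condition != "no_delta"]))
})

test_that("fuzzy intrusion matching tolerates one edit and stays off by
           default", {
  ds <- small_dataset(n_subjects = 10, seed = 5)
  out <- ds$outcomes[ds$outcomes$condition == "delta_target", ][1:3, ]
  tgt1 <- ds$stimuli$delta_target[match(out$quartet_id[1], ds$stimuli$id)]
  out$base_response <- c(paste0(tgt1, "x"), NA, "zzz")
  exact <- intrusion_rate(out, stimuli = ds$stimuli)
  fuzzy <- intrusion_rate(out, stimuli = ds$stimuli, fuzzy_match = TRUE)
  expect_equal(sum(exact$intrusion_rate), 0)
  expect_equal(sum(fuzzy$intrusion_rate), 1)
})
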