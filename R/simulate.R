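#' Simulation parameters for the reminder-based generative model
#'
#' Encodes a generative account of relatedness-dependent recall: during
#' secondary-pair learning a reminder of the base pair occurs with
#' probability `plogis(gamma0 + gamma1 * rel)`; a reminder adds `delta` to
#' the base-recall logit and couples base and secondary final-test outcomes
#' through a shared latent Gaussian with correlation `rho`. Base recall
#' success has probability
#' `plogis(beta0 + beta_cond + beta_rel * rel + delta * R - phi * [48hr]
#'  - kappa * [delta_target & 5min])`,
#' where `rel` is the condition-appropriate relatedness (target relatedness
#' in `delta_target`, cue relatedness in `delta_cue`, their sum in
#' `delta_both`, 1 in `no_delta`, 0 for the unshown control). Learning speed
#' in retrieval mode is `1 + Geometric(plogis(lambda0 + lambda1 * rel))`
#' trials to criterion, and failed base tests in `delta_target` intrude the
#' secondary target with probability `iota`.
#'
#' @param n_subjects Subjects to simulate (multiple of 5; default 200, the
#'   design's counterbalance-complete sample size).
#' @param delay `"48hr"` or `"5min"` retention interval.
#' @param learning_mode `"retrieval"` (retrieval to criterion) or `"study"`
#'   (yoked study-only; no learning measure).
#' @param beta0 Baseline logit of base-pair recall before the delay offset.
#' @param beta_cond Named numeric of per-condition logit offsets
#'   (`control` is the reference, 0).
#' @param beta_rel Relatedness slope on the recall logit.
#' @param gamma0,gamma1 Reminder-probability logit intercept and relatedness
#'   slope.
#' @param delta Strengthening boost (logit units) given a reminder.
#' @param rho Latent outcome correlation given a reminder, in `[0, 1]`.
#' @param kappa Retrieval-competition penalty applied in `delta_target` at
#'   the 5-min delay only.
#' @param phi Forgetting offset applied at the 48-hr delay.
#' @param lambda0,lambda1 Learning-rate logit intercept and relatedness slope.
#' @param iota Intrusion probability given a base-test failure in
#'   `delta_target`.
#' @param seed Integer seed fixing the full dataset.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_subjects = 200, delay = c("48hr", "5min"),
                       learning_mode = c("retrieval", "study"),
                       beta0 = 1.0,
                       beta_cond = c(no_delta = 1.5, delta_target = 0.1,
                                     delta_cue = 0.6, delta_both = -0.6,
                                     control = 0),
                       beta_rel = 0.4, gamma0 = -1, gamma1 = 2.5,
                       delta = 1.0, rho = 0.5, kappa = 1.0, phi = 1.2,
                       lambda0 = -0.5, lambda1 = 1.5, iota = 0.2,
                       seed = 1L) {
  delay <- match.arg(delay)
  learning_mode <- match.arg(learning_mode)
  stopifnot(setequal(names(beta_cond), retro_conditions()))
  assert_scalar_number(rho, "rho", 0, 1)
  assert_scalar_number(iota, "iota", 0, 1)
  structure(list(
    n_subjects = n_subjects, delay = delay, learning_mode = learning_mode,
    beta0 = beta0, beta_cond = beta_cond[retro_conditions()],
    beta_rel = beta_rel, gamma0 = gamma0, gamma1 = gamma1, delta = delta,
    rho = rho, kappa = kappa, phi = phi, lambda0 = lambda0,
    lambda1 = lambda1, iota = iota, seed = as.integer(seed)),
    class = "sim_params")
}

#' Named parameter presets
#'
#' `"paper_stylized"` is tuned so that simulated condition-level memorability
#' reproduces the qualitative ordering observed with a narrow, high-related
#' stimulus range at a 48-hr delay (no-delta > delta-cue > delta-target >
#' delta-both > control). `"null"` removes every condition, relatedness,
#' reminder and coupling effect, for calibration studies.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params` list.
#' @export
preset_params <- function(name = c("paper_stylized", "null"), ...) {
  name <- match.arg(name)
  base <- if (name == "paper_stylized") list() else list(
    beta_cond = c(no_delta = 0, delta_target = 0, delta_cue = 0,
                  delta_both = 0, control = 0),
    beta_rel = 0, gamma1 = 0, delta = 0, rho = 0, kappa = 0)
  args <- utils::modifyList(base, list(...))
  do.call(sim_params, args)
}

#' Write / read simulation parameters as YAML
#'
#' @param params A [sim_params()] object.
#' @param path File path.
#' @return `read_sim_params()` returns a `sim_params` object.
#' @export
write_sim_params <- function(params, path) {
  raw <- unclass(params)
  raw$beta_cond <- as.list(raw$beta_cond)  # keep names in YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$beta_cond <- unlist(raw$beta_cond)
  do.call(sim_params, raw)
}

#' Generate a synthetic free-association network
#'
#' Sparse directed stand-in for free-association norms: each word's outgoing
#' strengths are drawn and scaled to sum below 1, and a known chain
#' (`chain01 -> chain02 -> chain03 -> chain04`, strengths 0.5, 0.4, 0.3) is
#' planted so that multi-step metrics are exercised with hand-computable
#' values (exposed in the `planted_chain` attribute).
#'
#' @param n_words Number of words (at least 10).
#' @param mean_out_degree Average out-degree of the random part.
#' @param seed Integer seed.
#' @return An [assoc_network()].
#' @export
generate_network <- function(n_words = 100, mean_out_degree = 4, seed = 1L) {
  if (n_words < 10) abort("`n_words` must be at least 10.")
  withr::local_seed(seed)
  words <- sprintf("w%04d", seq_len(n_words))
  chain <- tibble(source = words[1:3], target = words[2:4],
                  strength = c(0.5, 0.4, 0.3))
  rows <- vector("list", n_words)
  for (i in seq_len(n_words)) {
    k <- min(n_words - 1L, max(1L, rpois(1, mean_out_degree)))
    tgt <- sample(setdiff(seq_len(n_words), i), k)
    raw <- rgamma(k, shape = 1)
    # planted chain edges reserve strength on their source nodes
    reserved <- if (i <= 3) chain$strength[i] else 0
    total <- runif(1, 0.3, 1 - 1e-6) * (1 - reserved)
    s <- raw / sum(raw) * total
    keep <- s > 1e-4
    rows[[i]] <- tibble(source = words[i], target = words[tgt[keep]],
                        strength = s[keep])
  }
  edges <- dplyr::bind_rows(rows)
  edges <- dplyr::anti_join(edges, chain, by = c("source", "target"))
  edges <- dplyr::bind_rows(chain, edges)
  net <- assoc_network(edges)
  attr(net, "planted_chain") <- chain
  net
}

#' Generate a quasi-evenly spaced pool of relation pairs
#'
#' Relatedness values cover `[lo, hi]` with endpoints hit exactly and the
#' maximum gap bounded by twice the even spacing; interior values are
#' jittered around an even grid. Words are synthetic and unique.
#'
#' @param lo,hi Range of relatedness values (`lo < hi`).
#' @param n_pairs Number of pairs (default 90).
#' @param seed Integer seed.
#' @return Tibble with columns `word_a`, `word_b`, `relatedness`.
#' @export
generate_pair_pool <- function(lo = 0.03, hi = 0.96, n_pairs = 90,
                               seed = 1L) {
  if (!(lo < hi)) abort("`lo` must be smaller than `hi`.")
  withr::local_seed(seed)
  grid <- seq(lo, hi, length.out = n_pairs)
  rel <- grid
  if (n_pairs > 2) {
    step <- (hi - lo) / (n_pairs - 1)
    mid <- seq(2, n_pairs - 1)
    rel[mid] <- grid[mid] + runif(length(mid), -0.4, 0.4) * step
  }
  tibble(word_a = sprintf("base%03d", seq_len(n_pairs)),
         word_b = sprintf("second%03d", seq_len(n_pairs)),
         relatedness = rel)
}

# Condition-appropriate relatedness driving reminders, recall and learning.
condition_relatedness <- function(condition, r_cue, r_target) {
  dplyr::case_when(
    condition == "delta_target" ~ r_target,
    condition == "delta_cue" ~ r_cue,
    condition == "delta_both" ~ r_cue + r_target,
    condition == "no_delta" ~ 1,
    TRUE ~ 0)
}

#' Simulate a full two-list experiment
#'
#' Draws final-test outcomes (and, in retrieval mode, trials to criterion)
#' for every (subject, pair) under the reminder-based generative model of
#' [sim_params()]. Control pairs are unshown in the secondary phase: they
#' receive no reminder, no secondary outcome and no learning measure.
#'
#' @param params A [sim_params()] object.
#' @param stimuli A [build_stimulus_grid()] stimulus set.
#' @param plan Optional [counterbalance()] plan; built from `params$n_subjects`
#'   when omitted.
#' @return A `retro_dataset` list with elements `outcomes` (tibble: `subject`,
#'   `quartet_id`, `condition`, `rel`, `reminder`, `base_correct`,
#'   `secondary_correct`, `base_response`, `trials_to_criterion`), `stimuli`,
#'   `plan`, `params`, and `excluded` (empty until [exclude_subjects()]).
#' @export
simulate_experiment <- function(params, stimuli, plan = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(plan)) plan <- counterbalance(stimuli, params$n_subjects)
  withr::local_seed(params$seed)
  d48 <- as.numeric(params$delay == "48hr")
  d5 <- 1 - d48

  df <- dplyr::left_join(
    as_tibble(plan),
    dplyr::select(as_tibble(stimuli), "id", "r_cue", "r_target", "target",
                  "delta_target"),
    by = c("quartet_id" = "id"))
  df$rel <- condition_relatedness(df$condition, df$r_cue, df$r_target)
  shown <- df$condition != "control"

  n <- nrow(df)
  p_rem <- ifelse(shown, plogis(params$gamma0 + params$gamma1 * df$rel), 0)
  reminder <- rbinom(n, 1, p_rem)

  logit_base <- params$beta0 +
    unname(params$beta_cond[df$condition]) +
    params$beta_rel * df$rel +
    params$delta * reminder -
    params$phi * d48 -
    params$kappa * as.numeric(df$condition == "delta_target") * d5
  p_base <- plogis(logit_base)
  logit_sec <- params$beta0 + params$beta_rel * df$rel +
    params$delta * reminder - params$phi * d48
  p_sec <- plogis(logit_sec)

  # coupled outcomes: shared latent Gaussian when a reminder occurred
  u1 <- rnorm(n)
  u2 <- ifelse(reminder == 1,
               params$rho * u1 + sqrt(1 - params$rho^2) * rnorm(n),
               rnorm(n))
  base_correct <- as.integer(u1 < qnorm(p_base))
  secondary_correct <- ifelse(shown, as.integer(u2 < qnorm(p_sec)),
                              NA_integer_)

  intrude <- df$condition == "delta_target" & base_correct == 0 &
    rbinom(n, 1, params$iota) == 1
  base_response <- dplyr::case_when(
    base_correct == 1 ~ df$target,
    intrude ~ df$delta_target,
    TRUE ~ NA_character_)

  trials_to_criterion <- rep(NA_integer_, n)
  if (params$learning_mode == "retrieval") {
    p_learn <- plogis(params$lambda0 + params$lambda1 * df$rel)
    trials_to_criterion[shown] <- 1L + rgeom(sum(shown), p_learn[shown])
  }

  outcomes <- tibble(
    subject = df$subject, quartet_id = df$quartet_id,
    condition = df$condition, rel = df$rel, reminder = reminder,
    base_correct = base_correct, secondary_correct = secondary_correct,
    base_response = base_response,
    trials_to_criterion = trials_to_criterion)

  structure(list(outcomes = outcomes, stimuli = stimuli, plan = plan,
                 params = params, excluded = integer(0)),
            class = "retro_dataset")
}

#' @export
print.retro_dataset <- function(x, ...) {
  cat(sprintf(
    "<retro_dataset: %d subjects x %d quartets, %s delay, %s learning%s>\n",
    length(unique(x$outcomes$subject)), nrow(x$stimuli), x$params$delay,
    x$params$learning_mode,
    if (length(x$excluded)) sprintf(", %d excluded", length(x$excluded))
    else ""))
  invisible(x)
}

#' Export a simulated dataset as plain CSV files
#'
#' Writes `outcomes.csv`, `stimuli.csv` and `plan.csv` into `dir`. Output is
#' byte-identical for identical datasets, so a seed fully reproduces the
#' export.
#'
#' @param dataset A `retro_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset_csv <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("outcomes.csv", "stimuli.csv", "plan.csv"))
  readr::write_csv(dataset$outcomes, paths[1], progress = FALSE)
  readr::write_csv(as_tibble(dataset$stimuli), paths[2], progress = FALSE)
  readr::write_csv(as_tibble(dataset$plan), paths[3], progress = FALSE)
  invisible(paths)
}
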