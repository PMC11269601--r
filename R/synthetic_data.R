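# Synthetic keypress-data generation with known ground truth: emulates the
# four-group design, lognormal latency noise, warm-up inflation, and error
# presses, so the whole pipeline is testable without any external data.

#' Configuration for the synthetic keypress generator
#'
#' @param model Generating model name (see [model_names()]).
#' @param params Named true parameter vector for `model`.  The defaults are
#'   for the online generator and were chosen to place the curves in the
#'   range of the observed group means: `a = 1800`, `b = 2500` ms,
#'   `c = 0.004`, `k = 0.12`, within-trial RI slope `y = 20` ms, residual
#'   slope `z = 8` ms.
#' @param n_participants Participants per group.
#' @param noise_cv Lognormal noise level: the standard deviation of the log
#'   sequence RT about the generating curve (for small values this is the
#'   coefficient of variation).  Keypress latencies inherit the same
#'   scatter, recentred so the sequence-level geometric mean is exact.
#' @param warmup_inflation Multiplicative RT factor (`>= 1`) applied to the
#'   first (warm-up) sequence of every trial.
#' @param error_prob Per-keypress probability that a given press of the
#'   upcoming sequence is preceded by an error press (so the expected error
#'   count per sequence is `5 * error_prob`).
#' @param error_slope Per-position increment of `error_prob` within a trial,
#'   emulating reactive inhibition leaking into the error rate.
#' @param seed Integer seed; every draw in the generator flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(model = "online",
                         params = c(a = 1800, b = 2500, c = 0.004, k = 0.12,
                                    y = 20, z = 8),
                         n_participants = 20L,
                         noise_cv = 0.1,
                         warmup_inflation = 1.5,
                         error_prob = 0.04,
                         error_slope = 0,
                         seed = 1L) {
  stopifnot(noise_cv >= 0, error_prob >= 0, error_prob < 1,
            warmup_inflation >= 1, n_participants >= 1)
  model <- model_spec(model)
  check_params(model, params)
  structure(list(model = model$name, params = params,
                 n_participants = as.integer(n_participants),
                 noise_cv = noise_cv, warmup_inflation = warmup_inflation,
                 error_prob = error_prob, error_slope = error_slope,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic config: %s generator, %d participants/group, noise CV %.3f,\n  warm-up x%.2f, error prob %.3f (+%.4f/position), seed %d\n",
    x$model, x$n_participants, x$noise_cv, x$warmup_inflation,
    x$error_prob, x$error_slope, x$seed))
  cat("  true params:",
      paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", "),
      "\n")
  invisible(x)
}

# Latencies for one correct sequence: base rt/5, sequence-level lognormal
# factor exp(eta), plus keypress-level scatter recentred so the geometric
# mean (hence the scored sequence RT) equals rt * exp(eta) exactly.
sequence_latencies <- function(rt, sigma) {
  eta <- if (sigma > 0) stats::rnorm(1L, 0, sigma) else 0
  eps <- if (sigma > 0) stats::rnorm(5L, 0, sigma) else numeric(5L)
  (rt / 5) * exp(eta + eps - mean(eps))
}

# Error presses preceding a sequence: each of the 5 presses is preceded by
# an error press with probability p.  Error keys are drawn from {1, 2, 3}
# (never the target's first key), so an error press can never extend a
# partial match of 4-1-3-2-4.
error_presses <- function(p) {
  n <- stats::rbinom(1L, 5L, min(max(p, 0), 0.99))
  if (n == 0L) return(integer(0))
  sample(c(1L, 2L, 3L), n, replace = TRUE)
}

#' Generate one participant's keypress log
#'
#' For each scheduled correct sequence the generator emits the five target
#' presses with latencies whose geometric mean times five equals the
#' model-predicted RT at that schedule row, perturbed by lognormal noise
#' (and multiplied by `warmup_inflation` on each trial's first sequence,
#' which is not part of the modeled schedule and carries the predicted RT
#' of the trial's first modeled sequence).  Error presses are inserted
#' before sequences with per-press probability
#' `error_prob + error_slope * (position - 1)`.
#'
#' @param config A [synth_config()].
#' @param spec A [make_group_spec()] group specification.
#' @param participant Participant identifier.
#' @return Data frame in the keypress dialect: `participant`, `group`,
#'   `phase`, `trial`, `press_index`, `key`, `latency_ms`.
#' @export
generate_participant <- function(config, spec, participant = "p1") {
  stopifnot(inherits(config, "synth_config"), inherits(spec, "group_spec"))
  schedule <- build_schedule(spec)
  skill <- predict_rt(config$model, config$params, schedule)
  per_trial <- spec$seqs_per_trial - 1L
  n_trials <- spec$n_train_trials + spec$n_test_trials

  keys <- integer(0); lats <- numeric(0)
  phase <- character(0); trial <- integer(0)
  for (tc in seq_len(n_trials)) {
    rows <- which(schedule$trial_cum == tc)
    ph <- schedule$phase[rows[1L]]
    tr <- schedule$trial[rows[1L]]
    t_keys <- integer(0); t_lats <- numeric(0)
    # warm-up sequence: RT of the trial's first modeled sequence, inflated
    rts <- c(skill[rows[1L]] * config$warmup_inflation, skill[rows])
    for (pos in seq_along(rts)) {
      p_err <- config$error_prob + config$error_slope * (pos - 1)
      errs <- error_presses(p_err)
      if (length(errs)) {
        t_keys <- c(t_keys, errs)
        t_lats <- c(t_lats, (rts[pos] / 5) *
                      exp(stats::rnorm(length(errs), 0, max(config$noise_cv, 0.01))))
      }
      t_keys <- c(t_keys, TARGET_SEQUENCE)
      t_lats <- c(t_lats, sequence_latencies(rts[pos], config$noise_cv))
    }
    keys <- c(keys, t_keys); lats <- c(lats, t_lats)
    phase <- c(phase, rep(ph, length(t_keys)))
    trial <- c(trial, rep(tr, length(t_keys)))
  }
  press_index <- stats::ave(seq_along(keys),
                            paste(phase, trial), FUN = seq_along)
  data.frame(participant = participant, group = spec$label, phase = phase,
             trial = trial, press_index = press_index, key = keys,
             latency_ms = lats, stringsAsFactors = FALSE)
}

#' Generate a complete four-group synthetic dataset
#'
#' Independent participants for each of the four groups (S30, S10, M30,
#' M10), reproducible from the config's seed, with the generating model and
#' true parameters recorded alongside.
#'
#' @param config A [synth_config()].
#' @param groups Group labels to generate (default all four).
#' @return A list of class `synth_dataset` with `keypresses` (one keypress
#'   data frame, all groups stacked) and `truth` (the config, i.e. model,
#'   parameters, noise settings, seed).
#' @export
generate_dataset <- function(config, groups = c("S30", "S10", "M30", "M10")) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  out <- vector("list", length(groups) * config$n_participants)
  i <- 0L
  for (g in groups) {
    spec <- make_group_spec(g)
    for (p in seq_len(config$n_participants)) {
      i <- i + 1L
      out[[i]] <- generate_participant(config, spec,
                                       participant = sprintf("%s_p%02d", g, p))
    }
  }
  structure(list(keypresses = do.call(rbind, out), truth = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d keypresses, %d participants, groups %s\n",
              nrow(x$keypresses), length(unique(x$keypresses$participant)),
              paste(unique(x$keypresses$group), collapse = ", ")))
  print(x$truth)
  invisible(x)
}

#' Generate and preprocess one group's averaged series
#'
#' Convenience wrapper: generate a group's keypress data, score it, drop
#' warm-ups, and average over participants — the series [fit_model()]
#' consumes.
#'
#' @param config A [synth_config()].
#' @param group Group label.
#' @return An `averaged_series`.
#' @export
synth_averaged_series <- function(config, group) {
  spec <- make_group_spec(group)
  ds <- generate_dataset(config, groups = group)
  seqs <- score_sequences(ds$keypresses)
  average_over_participants(remove_warmups(seqs), build_schedule(spec))
}
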