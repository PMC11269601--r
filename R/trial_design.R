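# Experimental design: the 2x2 finger-tapping study (sequences per trial x
# break length), its observation schedule, and the design constants consumed
# by the skill and reactive-inhibition equations.

#' Group specification for the 2x2 sequence-learning design
#'
#' The experiment crosses sequences-per-trial (massed: 15, spaced: 5,
#' counting the warm-up sequence) with inter-trial break length (10 s or
#' 30 s).  Every group completes 180 correct training sequences, a 300 s
#' rest, and 30 correct test sequences, so spaced groups run three times as
#' many trials as massed groups.
#'
#' @param label Group label: one of `"S30"`, `"S10"` (spaced, 5 sequences
#'   per trial), `"M30"`, `"M10"` (massed, 15 sequences per trial); the
#'   number gives the break length in seconds.
#' @return An object of class `group_spec`: a list with `label`,
#'   `seqs_per_trial`, `break_s`, `n_train_trials`, `n_test_trials`,
#'   and `rest_s` (seconds of post-training rest, always 300).
#' @examples
#' make_group_spec("M10")
#' @export
make_group_spec <- function(label) {
  valid <- c("S30", "S10", "M30", "M10")
  if (!(is.character(label) && length(label) == 1L && label %in% valid)) {
    stop("unknown group label ", deparse(label),
         "; valid labels are: ", paste(valid, collapse = ", "))
  }
  spaced <- substr(label, 1, 1) == "S"
  seqs_per_trial <- if (spaced) 5L else 15L
  spec <- list(
    label          = label,
    seqs_per_trial = seqs_per_trial,
    break_s        = as.integer(substr(label, 2, 3)),
    n_train_trials = 180L %/% seqs_per_trial,
    n_test_trials  = 30L %/% seqs_per_trial,
    rest_s         = 300L
  )
  class(spec) <- "group_spec"
  spec
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf(
    "Group %s: %d sequences/trial, %d s breaks, %d training + %d test trials, %d s rest\n",
    x$label, x$seqs_per_trial, x$break_s, x$n_train_trials, x$n_test_trials,
    x$rest_s))
  invisible(x)
}

#' Total number of breaks in a group's session
#'
#' Counts every between-trial break during training, the single 300 s rest
#' between training and test, and every between-trial break during the test
#' phase.  This is the `Btot` that scales the per-break learning parameter
#' `j` in the HybridJ model: for massed groups, 11 training breaks + the
#' rest + 1 test break = 13.
#'
#' @param spec A `group_spec` from [make_group_spec()].
#' @return Integer break count.
#' @examples
#' count_breaks(make_group_spec("M30"))  # 13
#' @export
count_breaks <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  (spec$n_train_trials - 1L) + 1L + (spec$n_test_trials - 1L)
}

#' Design constants for a group
#'
#' `Stot` is the total number of modeled sequences (all correct sequences
#' minus one warm-up per trial), `Btot` the total break count including the
#' rest period, and `n_obs` the number of averaged RT observations entering
#' each fit (equal to `Stot`).
#'
#' @inheritParams count_breaks
#' @return A list with `Stot`, `Btot`, `n_obs`.
#' @export
design_constants <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  n_trials <- spec$n_train_trials + spec$n_test_trials
  Stot <- n_trials * (spec$seqs_per_trial - 1L)
  list(Stot = Stot, Btot = count_breaks(spec), n_obs = Stot)
}

#' Build the observation schedule for a group
#'
#' One row per modeled (non-warm-up) correct sequence, in execution order
#' across the training and test phases.  The index variables are those the
#' model equations consume:
#' \describe{
#'   \item{trial}{phase-local trial number (training trial `T`, or test
#'     trial during the test phase).}
#'   \item{trial_cum}{trial number cumulative across both phases; the skill
#'     functions of the offline and hybrid models keep accruing break
#'     learning through the rest and the test phase via this index.}
#'   \item{trial_test}{test-phase trial number `T_test`, 1-based; `NA`
#'     during training.  The reactive-inhibition equation restarts its
#'     residual term on this index because the 300 s rest is assumed to
#'     dissipate accumulated inhibition completely.}
#'   \item{st}{modeled within-trial sequence number `ST` (1..4 spaced,
#'     1..14 massed); 1 on the sequence after each trial's removed warm-up.}
#'   \item{s}{modeled sequence number `S`, cumulative across phases.}
#'   \item{x}{phase dummy: 0 for training, 1 for test.}
#' }
#'
#' @inheritParams count_breaks
#' @return A data frame of class `apex_schedule` with columns `group`,
#'   `phase`, `trial`, `trial_cum`, `trial_test`, `st`, `s`, `x`, and the
#'   group's [design_constants()] attached as attribute `"constants"`.
#' @examples
#' sch <- build_schedule(make_group_spec("M10"))
#' nrow(sch)                      # 196 modeled sequences
#' attr(sch, "constants")$Btot    # 13 breaks
#' @export
build_schedule <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  per_trial <- spec$seqs_per_trial - 1L   # warm-up removed
  n_train <- spec$n_train_trials
  n_test <- spec$n_test_trials
  n_trials <- n_train + n_test

  trial_cum <- rep(seq_len(n_trials), each = per_trial)
  is_test <- trial_cum > n_train
  sched <- data.frame(
    group      = spec$label,
    phase      = ifelse(is_test, "test", "train"),
    trial      = ifelse(is_test, trial_cum - n_train, trial_cum),
    trial_cum  = trial_cum,
    trial_test = ifelse(is_test, trial_cum - n_train, NA_integer_),
    st         = rep(seq_len(per_trial), times = n_trials),
    s          = seq_len(n_trials * per_trial),
    x          = as.integer(is_test),
    stringsAsFactors = FALSE
  )
  attr(sched, "constants") <- design_constants(spec)
  class(sched) <- c("apex_schedule", "data.frame")
  sched
}

# Constants of a schedule, falling back to recomputation from its group
# column if the attribute was stripped (e.g. by subsetting).
schedule_constants <- function(schedule) {
  consts <- attr(schedule, "constants")
  if (is.null(consts)) {
    consts <- design_constants(make_group_spec(schedule$group[1L]))
  }
  consts
}
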