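# Preprocessing of raw keypress logs: sequence scoring against the target
# 4-1-3-2-4, geometric-mean sequence RTs, warm-up removal, error summaries,
# and participant averaging.

# Target keypress sequence.  It has no proper border (no prefix equals a
# suffix), so completed matches can never overlap.
TARGET_SEQUENCE <- c(4L, 1L, 3L, 2L, 4L)

#' Sequence RT from five keypress latencies
#'
#' Latencies are log-transformed, averaged over the five presses of the
#' sequence, anti-logged, and multiplied by five: i.e. five times the
#' geometric mean.  The log transform damps the influence of a single slow
#' press relative to an arithmetic mean.  (Any log base gives the same
#' geometric mean; natural log is used.)
#'
#' @param latencies Numeric vector of exactly 5 positive inter-keypress
#'   latencies (ms).
#' @return The sequence RT in ms.
#' @examples
#' sequence_rt(rep(200, 5))           # 1000
#' sequence_rt(c(100, 100, 100, 100, 1600))  # 5 * 100 * 16^(1/5)
#' @export
sequence_rt <- function(latencies) {
  if (length(latencies) != 5L) {
    stop("a correct sequence has exactly 5 keypress latencies; got ",
         length(latencies))
  }
  if (any(!is.finite(latencies)) || any(latencies <= 0)) {
    stop("keypress latencies must be positive and finite")
  }
  5 * exp(mean(log(latencies)))
}

# Match one trial's presses against the target.  Matching is greedy
# left-to-right; an incorrect press resets the partial match (and is then
# re-tried as a potential sequence start).  Every press not belonging to a
# completed sequence counts as an error press attributed to the next
# completed sequence of the trial; trailing unmatched presses go to an
# overflow bucket (seq NA).
# Returns a list with per-sequence rt, n_errors_before, and trailing_errors.
match_trial <- function(keys, latencies, target = TARGET_SEQUENCE) {
  m <- length(target)
  n <- length(keys)
  rts <- numeric(0)
  errs <- integer(0)
  pos <- 0L          # matched prefix length
  start <- 0L        # index of first press of the current partial match
  pending_err <- 0L
  i <- 1L
  while (i <= n) {
    if (keys[i] == target[pos + 1L]) {
      if (pos == 0L) start <- i
      pos <- pos + 1L
      if (pos == m) {
        rts <- c(rts, sequence_rt(latencies[start:i]))
        errs <- c(errs, pending_err)
        pending_err <- 0L
        pos <- 0L
      }
      i <- i + 1L
    } else if (pos > 0L) {
      # partial match broken: its presses become errors; re-try this press
      pending_err <- pending_err + pos
      pos <- 0L
    } else {
      pending_err <- pending_err + 1L
      i <- i + 1L
    }
  }
  pending_err <- pending_err + pos   # unfinished partial at trial end
  list(rt = rts, n_errors_before = errs, trailing_errors = pending_err)
}

#' Score keypress logs into correct-sequence RTs
#'
#' Scans each participant-by-phase-by-trial press stream for completed
#' occurrences of the target sequence.  Each completed occurrence yields one
#' sequence RT ([sequence_rt()] of its five latencies); incorrect presses
#' accumulate into `n_errors_before` of the next completed sequence in the
#' same trial.  Incorrect presses after a trial's last completed sequence
#' are excluded from per-sequence error counts.  The first completed
#' sequence of every trial is flagged as a warm-up.
#'
#' @param presses Data frame with columns `participant`, `group`, `phase`,
#'   `trial`, `press_index`, `key` (1-4), `latency_ms`, ordered within
#'   participant and trial.
#' @param target Integer key sequence to match (default `c(4,1,3,2,4)`).
#' @param expected_seqs Optional expected number of completed sequences per
#'   trial (including the warm-up); trials falling short are flagged with a
#'   warning, never silently dropped.
#' @return Data frame with one row per completed sequence: `participant`,
#'   `group`, `phase`, `trial`, `seq_in_trial`, `rt_ms`, `n_errors_before`,
#'   `warmup`.
#' @export
score_sequences <- function(presses, target = TARGET_SEQUENCE,
                            expected_seqs = NULL) {
  req <- c("participant", "group", "phase", "trial", "press_index",
           "key", "latency_ms")
  missing <- setdiff(req, names(presses))
  if (length(missing)) {
    stop("presses is missing column(s): ", paste(missing, collapse = ", "))
  }
  presses <- presses[order(presses$participant, presses$phase != "train",
                           presses$trial, presses$press_index), ]
  idx <- interaction(presses$participant, presses$phase, presses$trial,
                     drop = TRUE)
  chunks <- split(seq_len(nrow(presses)), idx)
  out <- vector("list", length(chunks))
  short <- character(0)
  for (ci in seq_along(chunks)) {
    rows <- chunks[[ci]]
    res <- match_trial(presses$key[rows], presses$latency_ms[rows], target)
    nseq <- length(res$rt)
    if (!is.null(expected_seqs) && nseq < expected_seqs) {
      short <- c(short, names(chunks)[ci])
    }
    if (nseq == 0L) next
    out[[ci]] <- data.frame(
      participant = presses$participant[rows[1L]],
      group = presses$group[rows[1L]],
      phase = presses$phase[rows[1L]],
      trial = presses$trial[rows[1L]],
      seq_in_trial = seq_len(nseq),
      rt_ms = res$rt,
      n_errors_before = res$n_errors_before,
      warmup = seq_len(nseq) == 1L,
      stringsAsFactors = FALSE
    )
  }
  if (length(short)) {
    warning("trial(s) with fewer completed sequences than expected: ",
            paste(short, collapse = "; "))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(participant = character(0), group = character(0),
                      phase = character(0), trial = integer(0),
                      seq_in_trial = integer(0), rt_ms = numeric(0),
                      n_errors_before = integer(0), warmup = logical(0))
  }
  ord <- order(res$participant, res$phase != "train", res$trial,
               res$seq_in_trial)
  res <- res[ord, ]
  rownames(res) <- NULL
  res
}

#' Drop warm-up sequences
#'
#' Removes the first completed sequence of every training and test trial
#' (inflated RT and error rate) so the remaining rows align one-to-one with
#' the modeled schedule.
#'
#' @param seqs Sequence table from [score_sequences()].
#' @param schedule Optional schedule to validate alignment against: each
#'   participant must then have exactly `nrow(schedule)` modeled sequences.
#' @return The sequence table without warm-up rows.
#' @export
remove_warmups <- function(seqs, schedule = NULL) {
  out <- seqs[!seqs$warmup, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(schedule)) {
    counts <- table(out$participant)
    bad <- counts != nrow(schedule)
    if (any(bad)) {
      stop("modeled sequence counts misaligned with schedule (",
           nrow(schedule), " rows expected): ",
           paste(sprintf("%s=%d", names(counts)[bad], counts[bad]),
                 collapse = ", "))
    }
  }
  out
}

#' Error presses by within-trial sequence position
#'
#' Mean number of incorrect presses preceding each completed sequence,
#' tabulated by within-trial position (the warm-up position 1 reported like
#' any other, where its elevation is visible), plus per-group grand means
#' over training sequences, trials, and participants.
#'
#' @param seqs Sequence table from [score_sequences()].
#' @param phase Phase to summarise (default `"train"`).
#' @return A list with `by_position` (data frame: `group`, `seq_in_trial`,
#'   `mean_errors`, `se`, `n`) and `grand_mean` (data frame: `group`,
#'   `mean_errors`).
#' @export
error_rate_summary <- function(seqs, phase = "train") {
  d <- seqs[seqs$phase == phase, , drop = FALSE]
  if (!nrow(d)) stop("no sequences in phase ", deparse(phase))
  agg <- aggregate(n_errors_before ~ group + seq_in_trial, data = d,
                   FUN = function(v) c(mean = mean(v),
                                       se = stats::sd(v) / sqrt(length(v)),
                                       n = length(v)))
  by_position <- data.frame(group = agg$group, seq_in_trial = agg$seq_in_trial,
                            mean_errors = agg$n_errors_before[, "mean"],
                            se = agg$n_errors_before[, "se"],
                            n = agg$n_errors_before[, "n"])
  by_position <- by_position[order(by_position$group,
                                   by_position$seq_in_trial), ]
  rownames(by_position) <- NULL
  gm <- aggregate(n_errors_before ~ group, data = d, FUN = mean)
  names(gm)[2] <- "mean_errors"
  list(by_position = by_position, grand_mean = gm)
}

#' Correlation between error rate and within-trial position
#'
#' Pearson correlation over (position, error count) pairs for the modeled
#' (non-warm-up) positions, pooled across trials and participants.  A
#' positive correlation indicates that reactive inhibition shows up in the
#' error rate, not only in the correct-sequence RTs.
#'
#' @param seqs Sequence table from [score_sequences()].
#' @param positions Within-trial positions to include; defaults to every
#'   position from 2 (the warm-up position is excluded).
#' @param phase Phase to use (default `"train"`).
#' @return A list with `r`, `df`, `p_value`, `n`.
#' @export
error_seq_correlation <- function(seqs, positions = NULL, phase = "train") {
  d <- seqs[seqs$phase == phase, , drop = FALSE]
  if (is.null(positions)) positions <- 2:max(d$seq_in_trial)
  d <- d[d$seq_in_trial %in% positions, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 (position, error) pairs")
  if (stats::var(d$n_errors_before) == 0 || stats::var(d$seq_in_trial) == 0) {
    warning("zero variance; correlation reported as 0")
    return(list(r = 0, df = nrow(d) - 2L, p_value = NA_real_, n = nrow(d)))
  }
  ct <- stats::cor.test(d$seq_in_trial, d$n_errors_before)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p_value = ct$p.value, n = nrow(d))
}

#' Average modeled sequence RTs over participants
#'
#' Arithmetic mean and standard error of the modeled sequence RTs at each
#' schedule position; this participant-averaged series is what the models
#' are fitted to.
#'
#' @param modeled Warm-up-free sequence table ([remove_warmups()]) for one
#'   group.
#' @param schedule The group's [build_schedule()] schedule.
#' @return Data frame of class `averaged_series`: the schedule columns plus
#'   `rt_mean`, `rt_se`, `n_participants`.
#' @export
average_over_participants <- function(modeled, schedule) {
  modeled <- remove_warmups(modeled, schedule)   # validates alignment
  parts <- unique(modeled$participant)
  n_p <- length(parts)
  # participants are schedule-aligned: order each by phase/trial/position
  ord <- order(modeled$participant, modeled$phase != "train", modeled$trial,
               modeled$seq_in_trial)
  rt <- matrix(modeled$rt_ms[ord], nrow = nrow(schedule), ncol = n_p)
  out <- as.data.frame(schedule)
  out$rt_mean <- rowMeans(rt)
  out$rt_se <- if (n_p > 1) apply(rt, 1, stats::sd) / sqrt(n_p) else NA_real_
  out$n_participants <- n_p
  attr(out, "constants") <- schedule_constants(schedule)
  class(out) <- c("averaged_series", "data.frame")
  out
}
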