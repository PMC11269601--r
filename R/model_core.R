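# Model equations: power-exponential (APEX) skill curves for the online,
# offline, and hybrid accounts of sequence learning, plus the additive
# reactive-inhibition (RI) terms shared by all with-RI variants.

# Shift applied wherever a (T - 1)-style base would be raised to a negative
# power at T = 1.  A single named constant so the value appears exactly once.
EPSILON_SHIFT <- 0.9999999999

#' Epsilon-shifted practice index
#'
#' The offline and hybrid skill functions contain terms of the form
#' `(T - 1)^(-k)`, which are singular on the first trial.  Following the
#' convention of fitting `T - 0.9999999999` in place of `T - 1`, this
#' returns a strictly positive index (1e-10 at `t = 1`) so the skill value
#' stays finite; for any later trial the perturbation is numerically
#' negligible.
#'
#' @param t Trial-like index, `>= 1` (vectorised).
#' @return `t - 0.9999999999`.
#' @export
epsilon_shift <- function(t) {
  t - EPSILON_SHIFT
}

# Registry of the eight model variants.  h counts free parameters.
.model_registry <- list(
  offline_v1        = list(params = c("a", "b", "c", "k"),
                           has_ri = FALSE, default = TRUE),
  offline_v2        = list(params = c("a", "b", "c", "k", "y", "z"),
                           has_ri = TRUE, default = TRUE),
  offline_v1_offset = list(params = c("a", "b", "c", "k", "g"),
                           has_ri = FALSE, default = FALSE),
  offline_v2_offset = list(params = c("a", "b", "c", "k", "g", "y", "z"),
                           has_ri = TRUE, default = FALSE),
  online            = list(params = c("a", "b", "c", "k", "y", "z"),
                           has_ri = TRUE, default = TRUE),
  hybridJ           = list(params = c("a", "b", "c", "k", "j", "y", "z"),
                           has_ri = TRUE, default = TRUE),
  hybridE           = list(params = c("a", "b", "c", "k", "y", "z"),
                           has_ri = TRUE, default = TRUE),
  hybridP           = list(params = c("a", "b", "c", "k", "y", "z"),
                           has_ri = TRUE, default = TRUE)
)

#' Names of the available model variants
#'
#' @param default_only If `TRUE`, only the six variants entering the default
#'   model comparison (the two rest-offset offline variants are implemented
#'   but excluded from comparisons by default).
#' @return Character vector of model names.
#' @export
model_names <- function(default_only = FALSE) {
  nm <- names(.model_registry)
  if (default_only) nm <- nm[vapply(.model_registry, `[[`, TRUE, "default")]
  nm
}

#' Look up a model variant
#'
#' @param name One of [model_names()]: `"online"` (all learning during
#'   practice), `"offline_v1"`/`"offline_v2"` (all learning during breaks,
#'   without/with RI), `"offline_v1_offset"`/`"offline_v2_offset"` (rest
#'   period grants an extra RT offset `g`), `"hybridJ"` (a fitted number
#'   `j` of learning units per break), `"hybridE"` (exponential gains
#'   offline, power gains online), `"hybridP"` (the reverse).
#' @return A list of class `model_spec` with `name`, `param_names`,
#'   `has_ri`, and free-parameter count `h`.
#' @export
model_spec <- function(name) {
  if (inherits(name, "model_spec")) return(name)
  if (!(is.character(name) && length(name) == 1L &&
        name %in% names(.model_registry))) {
    stop("unknown model ", deparse(name), "; available models: ",
         paste(names(.model_registry), collapse = ", "))
  }
  entry <- .model_registry[[name]]
  structure(list(name = name, param_names = entry$params,
                 has_ri = entry$has_ri, h = length(entry$params)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s: parameters {%s} (h = %d)%s\n", x$name,
              paste(x$param_names, collapse = ", "), x$h,
              if (x$has_ri) ", with RI" else ", no RI"))
  invisible(x)
}

check_params <- function(model, params) {
  model <- model_spec(model)
  missing <- setdiff(model$param_names, names(params))
  if (length(missing)) {
    stop("model ", model$name, " requires parameter(s): ",
         paste(missing, collapse = ", "))
  }
  p <- params[model$param_names]
  bad <- p[setdiff(model$param_names, "j")] <= 0
  if (any(bad)) {
    stop("all parameters must be > 0; offending: ",
         paste(setdiff(model$param_names, "j")[bad], collapse = ", "))
  }
  if ("j" %in% model$param_names && p[["j"]] < 0) {
    stop("parameter j must be >= 0")
  }
  p
}

#' Reactive-inhibition RT increment
#'
#' RI accrues linearly over consecutively executed sequences within a trial
#' (slope `y`, zero on each trial's first modeled sequence) and, through its
#' incomplete dissipation during short breaks, linearly over trials (residual
#' slope `z`, zero on trial one).  The 300 s rest is assumed to resolve
#' residual RI completely, so during the test phase the residual term
#' restarts on the test-trial index:
#' \deqn{RT_{RI} = (1-X)\{(ST-1)y + (T-1)z\} + X\{(ST-1)y + (T_{test}-1)z\}.}
#'
#' @param params Named numeric vector containing `y` and `z` (ms per
#'   sequence / ms per trial).
#' @param schedule An [build_schedule()] schedule.
#' @return Numeric vector of RT increments (ms), one per schedule row.
#' @export
ri_rt <- function(params, schedule) {
  if (!all(c("y", "z") %in% names(params))) {
    stop("ri_rt requires parameters y and z")
  }
  y <- params[["y"]]; z <- params[["z"]]
  within <- (schedule$st - 1) * y
  resid_train <- (schedule$trial - 1) * z
  resid_test <- (ifelse(is.na(schedule$trial_test), 0, schedule$trial_test) - 1) * z
  (1 - schedule$x) * (within + resid_train) + schedule$x * (within + resid_test)
}

# APEX curve: a + b * exp(-c * u_exp) * u_pow^(-k).  Arguments may differ
# between the exponential and power components (hybridE / hybridP).
apex_curve <- function(a, b, c, k, u_exp, u_pow = u_exp) {
  a + b * exp(-c * u_exp) * u_pow^(-k)
}

#' Effective cumulative learning units (HybridJ)
#'
#' The HybridJ model allocates `j` sequence-learning units to every break
#' (offline learning) and shares the remaining `Stot - Btot*j` units evenly
#' across the `Stot` executed sequences (online learning):
#' \deqn{S' = S (S_{tot} - B_{tot} j)/S_{tot} + (T_{cum}-1) j.}
#' Units are conserved: on the last test sequence (`S = Stot`,
#' `T_cum - 1 = Btot`) the effective index `S'` equals `S` for any `j`.
#'
#' @param schedule An [build_schedule()] schedule.
#' @param j Learning units per break, in `[0, Stot/Btot]`.
#' @param consts Design constants; defaults to the schedule's own.
#' @return Numeric vector `S'`, one value per schedule row.
#' @export
effective_units <- function(schedule, j, consts = schedule_constants(schedule)) {
  if (j < 0 || j > consts$Stot / consts$Btot) {
    stop(sprintf("j must lie in [0, Stot/Btot] = [0, %.4f]; got %g",
                 consts$Stot / consts$Btot, j))
  }
  schedule$s * (consts$Stot - consts$Btot * j) / consts$Stot +
    (schedule$trial_cum - 1) * j
}

#' Predicted skill RT (latent, RI-free)
#'
#' Evaluates the model's skill curve over a schedule.  All variants are
#' power-exponential in their practice index: the online model practices on
#' the cumulative modeled-sequence count `S`; the offline variants on the
#' break count, i.e. the cumulative trial index minus one (epsilon-shifted
#' on trial one, see [epsilon_shift()]); HybridJ on the effective units
#' `S'`; HybridE takes exponential gains on breaks and power gains on `S`;
#' HybridP the reverse.  The offset variants subtract `g` during the test
#' phase, representing extra consolidation during the 300 s rest.
#'
#' @param model A model name or [model_spec()].
#' @param params Named numeric vector of the model's parameters (ms for
#'   `a`, `b`, `g`; rates `c`, `k` per practice unit; `j` units per break).
#' @param schedule An [build_schedule()] schedule.
#' @param consts Design constants; defaults to the schedule's own.
#' @return Numeric vector of latent skill RTs (ms).
#' @export
skill_rt <- function(model, params, schedule,
                     consts = schedule_constants(schedule)) {
  model <- model_spec(model)
  p <- check_params(model, params)
  tb <- epsilon_shift(schedule$trial_cum)   # break count, shifted at trial 1
  s <- schedule$s
  rt <- switch(model$name,
    online = apex_curve(p[["a"]], p[["b"]], p[["c"]], p[["k"]], s),
    offline_v1 = ,
    offline_v2 = apex_curve(p[["a"]], p[["b"]], p[["c"]], p[["k"]], tb),
    offline_v1_offset = ,
    offline_v2_offset =
      apex_curve(p[["a"]], p[["b"]], p[["c"]], p[["k"]], tb) -
        p[["g"]] * schedule$x,
    hybridJ = {
      sp <- effective_units(schedule, p[["j"]], consts)
      # S' can reach 0 at the j upper bound on the first row; guard the
      # power term with the same epsilon used for the trial index.
      apex_curve(p[["a"]], p[["b"]], p[["c"]], p[["k"]],
                 pmax(sp, 1 - EPSILON_SHIFT))
    },
    hybridE = apex_curve(p[["a"]], p[["b"]], p[["c"]], p[["k"]],
                         u_exp = tb, u_pow = s),
    hybridP = apex_curve(p[["a"]], p[["b"]], p[["c"]], p[["k"]],
                         u_exp = s, u_pow = tb)
  )
  unname(rt)
}

#' Predicted observed RT
#'
#' The observed-RT prediction is the latent skill curve plus, for with-RI
#' variants, the reactive-inhibition increment: achieved skill is directly
#' observable only on the first modeled sequence of training and of test,
#' where both RI terms are zero.
#'
#' @inheritParams skill_rt
#' @return Numeric vector of predicted sequence RTs (ms), one per row.
#' @examples
#' sch <- build_schedule(make_group_spec("S30"))
#' p <- c(a = 1800, b = 2500, c = 0.004, k = 0.12, y = 20, z = 8)
#' head(predict_rt("online", p, sch))
#' @export
predict_rt <- function(model, params, schedule,
                       consts = schedule_constants(schedule)) {
  model <- model_spec(model)
  rt <- skill_rt(model, params, schedule, consts)
  if (model$has_ri) rt <- rt + ri_rt(params, schedule)
  rt
}
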