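# Model fitting: bounded nonlinear least squares with a grid search over
# starting values, BIC model comparison, and the offline-learning
# proportion implied by the fitted HybridJ break-learning parameter.

#' Bayesian Information Criterion for a least-squares fit
#'
#' `BIC = n * ln(RSS/n) + h * ln(n)` (natural log): fit quality through the
#' residual sum of squares plus a penalty for free parameters.  Lower is
#' better.
#'
#' @param n Number of observations.
#' @param rss Residual sum of squares (ms^2); must be positive (a zero RSS
#'   is a degenerate perfect fit with no defined BIC).
#' @param h Number of free parameters.
#' @return The BIC value.
#' @examples
#' bic(10, 10, 2)  # 2 * log(10)
#' @export
bic <- function(n, rss, h) {
  stopifnot(n > 0, h >= 1)
  if (!is.finite(rss) || rss <= 0) {
    stop("rss must be positive and finite; BIC is undefined for a perfect fit")
  }
  n * log(rss / n) + h * log(n)
}

#' Default grid of starting values for the grid search
#'
#' The grid spans the plausible range of each parameter with margin: RT
#' levels `a`, `b` cover the hundreds-to-thousands of ms seen in sequence
#' RTs, the rates `c`, `k` cover four orders of magnitude, and the RI
#' slopes bracket the single-to-tens of ms per sequence/trial range.  `j`
#' starting points are expressed as fractions of its upper bound
#' `Stot/Btot` and scaled per group at fit time.
#'
#' @return Named list of numeric start-value vectors (`j` as fractions of
#'   its bound).
#' @export
default_grid <- function() {
  list(a = c(500, 1000, 2000, 3000),
       b = c(500, 1000, 2000),
       c = c(1e-4, 1e-3, 1e-2, 1e-1),
       k = c(1e-3, 1e-2, 1e-1, 0.5),
       y = c(1, 10, 30),
       z = c(0.5, 5, 20),
       g = c(10, 100),
       j_frac = c(0, 0.25, 0.5, 0.75))
}

# Lower/upper parameter bounds for a model.  Strict positivity is
# implemented as lower bound 1e-12; j ranges over [0, Stot/Btot].
param_bounds <- function(model, consts) {
  model <- model_spec(model)
  lower <- rep(1e-12, model$h)
  upper <- rep(Inf, model$h)
  names(lower) <- names(upper) <- model$param_names
  if ("j" %in% model$param_names) {
    lower[["j"]] <- 0
    upper[["j"]] <- consts$Stot / consts$Btot
  }
  list(lower = lower, upper = upper)
}

# Expand the start grid for a model into a matrix of start vectors.
start_matrix <- function(model, grid, consts) {
  model <- model_spec(model)
  cols <- lapply(model$param_names, function(p) {
    if (p == "j") grid$j_frac * consts$Stot / consts$Btot else grid[[p]]
  })
  names(cols) <- model$param_names
  as.matrix(expand.grid(cols, KEEP.OUT.ATTRS = FALSE))
}

#' Fit one model to a group's averaged sequence RTs
#'
#' Minimises the sum of squared deviations between the observed averaged
#' RTs and [predict_rt()] over the model's parameters, subject to bound
#' constraints (all parameters `> 0`; `j` in `[0, Stot/Btot]`).  An
#' extensive grid of starting values is screened first by its residual sum
#' of squares; bounded Levenberg-Marquardt descent
#' ([minpack.lm::nls.lm()]) is then run from the `n_local` most promising
#' starts, and the best solution (lowest RSS, ties broken by fewest
#' iterations then grid order) is returned.  The procedure is
#' deterministic: the same data and grid give the same fit.
#'
#' @param model Model name or [model_spec()].
#' @param series An `averaged_series` from [average_over_participants()],
#'   or a bare numeric vector of RTs aligned to `schedule`.
#' @param schedule The group's [build_schedule()] schedule (defaulted from
#'   `series` when it is an `averaged_series`).
#' @param grid Start-value grid, as [default_grid()].
#' @param n_local Number of screened grid starts from which full descent is
#'   run.
#' @param extra_starts Optional list of named parameter vectors appended to
#'   the descent set regardless of screening — e.g. a nested submodel's
#'   solution (with `j = 0`, say) so that a superset model can never end
#'   above it.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol Relative RSS convergence tolerance.
#' @return An object of class `apex_fit` with components `model`, `group`,
#'   `params` (named estimates), `rss`, `n`, `h`, `bic`, `n_starts`,
#'   `converged`, `fitted`, `observed`, `schedule`.  Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `plot()` and `simulate()`.
#' @export
fit_model <- function(model, series, schedule = NULL, grid = default_grid(),
                      n_local = 25L, extra_starts = NULL, max_iter = 1000L,
                      ftol = 1e-12) {
  model <- model_spec(model)
  if (inherits(series, "averaged_series")) {
    if (is.null(schedule)) schedule <- series
    observed <- series$rt_mean
  } else {
    observed <- as.numeric(series)
  }
  if (is.null(schedule)) stop("a schedule is required when series is a bare vector")
  if (length(observed) != nrow(schedule)) {
    stop("series length (", length(observed),
         ") does not match schedule rows (", nrow(schedule), ")")
  }
  consts <- schedule_constants(schedule)
  bounds <- param_bounds(model, consts)
  starts <- start_matrix(model, grid, consts)
  if (!is.null(extra_starts)) {
    extra <- do.call(rbind, lapply(extra_starts, function(p) {
      if (!all(model$param_names %in% names(p))) {
        stop("extra start missing parameter(s): ",
             paste(setdiff(model$param_names, names(p)), collapse = ", "))
      }
      pmin(pmax(p[model$param_names], bounds$lower), bounds$upper)
    }))
    starts <- rbind(starts, extra)
  }

  residual_fn <- function(par) {
    names(par) <- model$param_names
    observed - predict_rt(model, par, schedule, consts)
  }

  # screen: RSS at every grid start, cheap vectorised prediction; any
  # extra_starts bypass screening and are always refined
  grid_rss <- apply(starts, 1L, function(par) sum(residual_fn(par)^2))
  n_grid <- nrow(starts) - length(extra_starts)
  keep <- union(order(grid_rss[seq_len(n_grid)])[seq_len(min(n_local, n_grid))],
                if (length(extra_starts)) (n_grid + 1L):nrow(starts))

  best <- NULL
  for (si in keep) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[si, ], fn = residual_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = ftol, ptol = 1e-12,
                           maxfev = 10000L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    cand <- list(par = fit$par, rss = rss, niter = fit$niter,
                 converged = fit$info %in% 1:4, order = si)
    if (is.null(best) ||
        rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 &&
         (cand$niter < best$niter ||
          (cand$niter == best$niter && cand$order < best$order)))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    # no start yielded an evaluable fit; report the best raw grid point
    si <- keep[1L]
    best <- list(par = starts[si, ], rss = grid_rss[si], niter = 0L,
                 converged = FALSE, order = si)
  }
  params <- best$par
  names(params) <- model$param_names
  fitted_rt <- predict_rt(model, params, schedule, consts)
  structure(list(
    model = model$name, group = schedule$group[1L], params = params,
    rss = best$rss, n = length(observed), h = model$h,
    bic = bic(length(observed), best$rss, model$h),
    n_starts = nrow(starts), n_local = length(keep),
    converged = best$converged, fitted = fitted_rt, observed = observed,
    schedule = schedule, consts = consts
  ), class = "apex_fit")
}

#' Fit a set of models to all groups and compare by BIC
#'
#' Fits every model to every group's averaged series and tabulates the BIC
#' matrix with a per-model mean row; the lowest BIC per group (and the
#' lowest mean) marks the preferred model.
#'
#' @param dataset Named list of `averaged_series`, one per group.
#' @param models Model names to compare; defaults to the six variants of
#'   the standard comparison (rest-offset variants excluded).
#' @param ... Passed to [fit_model()].
#' @return An object of class `apex_comparison`: list with `bic` (group x
#'   model matrix plus `Mean` row), `fits` (nested list of `apex_fit`),
#'   `best_per_group`, `best_overall`, `failed` (cells whose optimiser did
#'   not converge).
#' @export
fit_all <- function(dataset, models = model_names(default_only = TRUE), ...) {
  stopifnot(length(dataset) >= 1, !is.null(names(dataset)))
  groups <- names(dataset)
  bicm <- matrix(NA_real_, nrow = length(groups), ncol = length(models),
                 dimnames = list(groups, models))
  fits <- stats::setNames(vector("list", length(groups)), groups)
  failed <- character(0)
  for (g in groups) {
    fits[[g]] <- stats::setNames(vector("list", length(models)), models)
    for (m in models) {
      f <- tryCatch(fit_model(m, dataset[[g]], ...), error = function(e) NULL)
      if (is.null(f)) {
        failed <- c(failed, paste(g, m, sep = ":"))
        next
      }
      if (!f$converged) failed <- c(failed, paste(g, m, sep = ":"))
      fits[[g]][[m]] <- f
      bicm[g, m] <- f$bic
    }
  }
  bic_tab <- rbind(bicm, Mean = colMeans(bicm))
  best_per_group <- apply(bicm, 1L, function(r) models[which.min(r)])
  structure(list(bic = bic_tab, fits = fits,
                 best_per_group = best_per_group,
                 best_overall = models[which.min(bic_tab["Mean", ])],
                 failed = failed),
            class = "apex_comparison")
}

#' Offline-learning proportion from the HybridJ break parameter
#'
#' `Btot * j` of the `Stot` sequence-learning units are allocated to breaks,
#' so the percentage of learning attributed to offline (break) learning is
#' `100 * Btot * j / Stot`.
#'
#' @param j Fitted learning units per break, in `[0, Stot/Btot]`.
#' @param consts Design constants ([design_constants()]), or a `group_spec`
#'   or schedule from which they are derived.
#' @return Percentage of learning allocated offline (0-100).
#' @examples
#' offline_proportion(13.42, design_constants(make_group_spec("M30")))  # 89.01
#' @export
offline_proportion <- function(j, consts) {
  if (inherits(consts, "group_spec")) consts <- design_constants(consts)
  if (inherits(consts, "data.frame")) consts <- schedule_constants(consts)
  if (j < 0 || j > consts$Stot / consts$Btot) {
    stop(sprintf("j must lie in [0, Stot/Btot] = [0, %.4f]; got %g",
                 consts$Stot / consts$Btot, j))
  }
  100 * consts$Btot * j / consts$Stot
}
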