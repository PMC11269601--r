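# S3 methods for fitted models and model comparisons.

#' @export
print.apex_fit <- function(x, ...) {
  cat(sprintf("%s model fit, group %s (%d observations)\n",
              x$model, x$group, x$n))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
      "\n")
  cat(sprintf("  RSS = %.4g ms^2, BIC = %.3f (h = %d)%s\n", x$rss, x$bic,
              x$h, if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' @export
summary.apex_fit <- function(object, ...) {
  res <- object$observed - object$fitted
  out <- list(fit = object,
              resid_summary = summary(res),
              rmse = sqrt(mean(res^2)),
              offline_pct = if (object$model == "hybridJ")
                offline_proportion(object$params[["j"]], object$consts)
              else NULL)
  class(out) <- "summary.apex_fit"
  out
}

#' @export
print.summary.apex_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE = %.2f ms, searched %d grid starts (%d refined)\n",
              x$rmse, x$fit$n_starts, x$fit$n_local))
  if (!is.null(x$offline_pct)) {
    cat(sprintf("  offline-learning proportion: %.1f%%\n", x$offline_pct))
  }
  cat("  residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' @export
coef.apex_fit <- function(object, ...) object$params

#' Predict sequence RTs from a fitted model
#'
#' @param object An `apex_fit`.
#' @param newdata Optional schedule to predict over; defaults to the fitted
#'   schedule.
#' @param type `"response"` for the observed-RT prediction (skill + RI), or
#'   `"skill"` for the latent achieved-skill curve.
#' @param ... Unused.
#' @return Numeric vector of predicted RTs (ms).
#' @export
predict.apex_fit <- function(object, newdata = NULL,
                             type = c("response", "skill"), ...) {
  type <- match.arg(type)
  sch <- if (is.null(newdata)) object$schedule else newdata
  if (type == "skill") skill_rt(object$model, object$params, sch)
  else predict_rt(object$model, object$params, sch)
}

#' @export
fitted.apex_fit <- function(object, ...) object$fitted

#' @export
residuals.apex_fit <- function(object, ...) object$observed - object$fitted

#' Simulate keypress data from a fitted model
#'
#' Generates synthetic keypress logs from the fitted parameters via the
#' synthetic-data generator, for parametric-bootstrap style checks.
#'
#' @param object An `apex_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param n_participants,noise_cv,... Passed to [synth_config()].
#' @return A list of `nsim` keypress data frames (invisibly a single data
#'   frame when `nsim = 1`).
#' @export
simulate.apex_fit <- function(object, nsim = 1, seed = 1L,
                              n_participants = 20L, noise_cv = 0.1, ...) {
  lapply(seq_len(nsim), function(i) {
    cfg <- synth_config(model = object$model, params = object$params,
                        n_participants = n_participants, noise_cv = noise_cv,
                        seed = seed + i - 1L, ...)
    generate_dataset(cfg, groups = object$group)$keypresses
  })
}

#' Plot a fitted model over its data
#'
#' Observed averaged sequence RTs (points, with standard-error bars when
#' available), the overall model prediction (solid line), and the latent
#' achieved-skill curve underneath (faint line).  The vertical dashed line
#' marks the rest period between training and test.
#'
#' @param x An `apex_fit`.
#' @param show_skill Draw the latent skill curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.apex_fit <- function(x, show_skill = TRUE, ...) {
  sch <- x$schedule
  se <- if (inherits(sch, "averaged_series")) sch$rt_se else NULL
  graphics::plot(sch$s, x$observed, pch = 16, cex = 0.5, col = "grey25",
                 xlab = "Modeled sequence", ylab = "Sequence RT (ms)",
                 main = sprintf("%s fit, group %s", x$model, x$group), ...)
  if (!is.null(se) && all(is.finite(se))) {
    graphics::segments(sch$s, x$observed - se, sch$s, x$observed + se,
                       col = "grey70")
  }
  if (show_skill) {
    graphics::lines(sch$s, skill_rt(x$model, x$params, sch),
                    col = grDevices::adjustcolor("steelblue", 0.4), lwd = 2)
  }
  graphics::lines(sch$s, x$fitted, col = "firebrick", lwd = 1.5)
  first_test <- min(sch$s[sch$x == 1])
  graphics::abline(v = first_test - 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
print.apex_comparison <- function(x, digits = 3, ...) {
  cat("BIC model comparison (lower is better)\n")
  tab <- formatC(x$bic, format = "f", digits = digits)
  best_col <- apply(x$bic, 1L, which.min)
  for (i in seq_len(nrow(tab))) {
    tab[i, best_col[i]] <- paste0(tab[i, best_col[i]], "*")
  }
  print(tab, quote = FALSE, right = TRUE)
  cat("* best in row;  best overall (mean BIC):", x$best_overall, "\n")
  if (length(x$failed)) {
    cat("non-converged cells:", paste(x$failed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.apex_comparison <- function(object, ...) {
  cat("Best model per group:\n")
  print(object$best_per_group)
  hj <- lapply(object$fits, `[[`, "hybridJ")
  hj <- hj[!vapply(hj, is.null, TRUE)]
  if (length(hj)) {
    cat("\nHybridJ offline-learning proportions:\n")
    for (g in names(hj)) {
      cat(sprintf("  %s: j = %.3f -> %.0f%% offline\n", g,
                  hj[[g]]$params[["j"]],
                  offline_proportion(hj[[g]]$params[["j"]], hj[[g]]$consts)))
    }
  }
  invisible(object)
}
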