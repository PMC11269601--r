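# Pipeline driver, plotting, and artifact I/O tying the modules together.

#' Run the full simulate -> preprocess -> fit -> compare pipeline
#'
#' Generates a synthetic four-group dataset, scores and averages it, fits
#' the requested models to every group, and returns the BIC comparison
#' together with the per-group fits.  Fully reproducible from the config's
#' seed; the seed and a hash of the configuration are embedded in the
#' result for provenance.
#'
#' @param config A [synth_config()].
#' @param models Models to compare (default: the six standard variants).
#' @param groups Groups to include.
#' @param out_dir Optional directory: when given, the averaged series
#'   (CSV), the BIC table (CSV), and the full fits (JSON) are written
#'   there.
#' @param ... Passed to [fit_model()].
#' @return A list of class `apex_pipeline` with `comparison`
#'   (`apex_comparison`), `series` (per-group `averaged_series`), `config`,
#'   `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = synth_config(),
                         models = model_names(default_only = TRUE),
                         groups = c("S30", "S10", "M30", "M10"),
                         out_dir = NULL, ...) {
  ds <- generate_dataset(config, groups = groups)
  seqs <- score_sequences(ds$keypresses)
  series <- stats::setNames(lapply(groups, function(g) {
    average_over_participants(
      remove_warmups(seqs[seqs$group == g, ]),
      build_schedule(make_group_spec(g)))
  }), groups)
  comparison <- fit_all(series, models = models, ...)
  res <- structure(list(comparison = comparison, series = series,
                        config = config, seed = config$seed,
                        config_hash = config_hash(config)),
                   class = "apex_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.apex_pipeline <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$seed, x$config_hash))
  print(x$comparison)
  invisible(x)
}

# Short provenance hash of a configuration (stable across sessions).
config_hash <- function(config) {
  txt <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                       digits = NA))
  # tiny polynomial rolling hash over the serialized config; enough for
  # provenance labels (stays below 2^53 so the arithmetic is exact)
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = res$seed, config_hash = res$config_hash)
  for (g in names(res$series)) {
    utils::write.csv(as.data.frame(res$series[[g]]),
                     file.path(out_dir, sprintf("series_%s.csv", g)),
                     row.names = FALSE)
  }
  bic_df <- data.frame(group = rownames(res$comparison$bic),
                       res$comparison$bic, check.names = FALSE)
  utils::write.csv(bic_df, file.path(out_dir, "bic_comparison.csv"),
                   row.names = FALSE)
  fits <- lapply(res$comparison$fits, function(by_model) {
    lapply(by_model, function(f) {
      if (is.null(f)) return(NULL)
      list(model = f$model, group = f$group, params = as.list(f$params),
           rss = f$rss, n = f$n, h = f$h, bic = f$bic,
           converged = f$converged)
    })
  })
  jsonlite::write_json(c(stamp, list(fits = fits)),
                       file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Plot error presses by within-trial sequence position
#'
#' One panel per group: mean error presses before each completed sequence
#' against its within-trial position, with standard-error bars.  The
#' elevated first position reflects the warm-up effect.
#'
#' @param summary Output of [error_rate_summary()].
#' @export
plot_error_rates <- function(summary) {
  bp <- summary$by_position
  groups <- unique(bp$group)
  old <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(old))
  for (g in groups) {
    d <- bp[bp$group == g, ]
    graphics::plot(d$seq_in_trial, d$mean_errors, type = "b", pch = 16,
                   ylim = range(0, d$mean_errors + d$se, na.rm = TRUE),
                   xlab = "Sequence within trial",
                   ylab = "Error presses before sequence", main = g)
    graphics::segments(d$seq_in_trial, d$mean_errors - d$se,
                       d$seq_in_trial, d$mean_errors + d$se, col = "grey60")
  }
  invisible(summary)
}

#' Plot latent achieved-skill curves across groups
#'
#' Overlays the fitted achieved-skill curves (RT with reactive inhibition
#' removed) of one model for several groups on a common sequence axis.
#'
#' @param fits Named list of `apex_fit` objects (one per group, same
#'   model).
#' @export
plot_skill_curves <- function(fits) {
  stopifnot(length(fits) >= 1)
  cols <- grDevices::hcl.colors(max(4, length(fits)), "Dark 2")
  skills <- lapply(fits, function(f) skill_rt(f$model, f$params, f$schedule))
  xmax <- max(vapply(fits, function(f) max(f$schedule$s), numeric(1)))
  ylim <- range(unlist(skills))
  graphics::plot(NULL, xlim = c(1, xmax), ylim = ylim,
                 xlab = "Modeled sequence", ylab = "Achieved skill RT (ms)",
                 main = sprintf("Achieved skill (%s model)",
                                fits[[1]]$model))
  for (i in seq_along(fits)) {
    graphics::lines(fits[[i]]$schedule$s, skills[[i]], col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = names(fits), col = cols[seq_along(fits)],
                   lwd = 2, bty = "n")
  invisible(fits)
}

#' Write a schedule or sequence table to CSV
#'
#' @param x A schedule, sequence table, or averaged series.
#' @param path Output file path.
#' @export
write_apex_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a keypress log CSV
#'
#' Expects the keypress dialect: `participant`, `group`, `phase`, `trial`,
#' `press_index`, `key`, `latency_ms`.
#'
#' @param path CSV file path.
#' @return Keypress data frame.
#' @export
read_keypress_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant", "group", "phase", "trial", "press_index", "key",
           "latency_ms")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop("keypress file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  d
}
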