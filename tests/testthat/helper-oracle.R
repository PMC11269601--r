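# Independent oracle: literal row-by-row transcription of each model
# equation, written with scalar arithmetic and no reuse of the package's
# prediction code.  Used to verify predict_rt() against the formulas.

oracle_predict <- function(model_name, p, schedule, consts) {
  n <- nrow(schedule)
  out <- numeric(n)
  for (i in seq_len(n)) {
    S <- schedule$s[i]
    ST <- schedule$st[i]
    Ttr <- schedule$trial[i]
    Tcum <- schedule$trial_cum[i]
    Ttest <- schedule$trial_test[i]
    X <- schedule$x[i]
    # the (T - 1) bases substitute T - 0.9999999999 to avoid 0^(-k)
    Tb <- Tcum - 0.9999999999

    skill <- switch(model_name,
      online = p[["a"]] + p[["b"]] * exp(-p[["c"]] * S) * S^(-p[["k"]]),
      offline_v1 = ,
      offline_v2 =
        p[["a"]] + p[["b"]] * exp(-p[["c"]] * Tb) * Tb^(-p[["k"]]),
      offline_v1_offset = ,
      offline_v2_offset =
        p[["a"]] + p[["b"]] * exp(-p[["c"]] * Tb) * Tb^(-p[["k"]]) -
          p[["g"]] * X,
      hybridJ = {
        Sp <- S * (consts$Stot - consts$Btot * p[["j"]]) / consts$Stot +
          (Tcum - 1) * p[["j"]]
        p[["a"]] + p[["b"]] * exp(-p[["c"]] * Sp) * Sp^(-p[["k"]])
      },
      hybridE =
        p[["a"]] + p[["b"]] * exp(-p[["c"]] * Tb) * S^(-p[["k"]]),
      hybridP =
        p[["a"]] + p[["b"]] * exp(-p[["c"]] * S) * Tb^(-p[["k"]]),
      stop("oracle: unknown model ", model_name)
    )

    has_ri <- model_name %in% c("online", "offline_v2", "offline_v2_offset",
                                "hybridJ", "hybridE", "hybridP")
    ri <- if (has_ri) {
      if (X == 0) {
        (ST - 1) * p[["y"]] + (Ttr - 1) * p[["z"]]
      } else {
        (ST - 1) * p[["y"]] + (Ttest - 1) * p[["z"]]
      }
    } else 0

    out[i] <- skill + ri
  }
  out
}

# Random-but-reasonable parameter draw for a model (j strictly inside its
# bound so the oracle never meets the S' = 0 edge case).
oracle_draw <- function(model_name, consts) {
  p <- c(a = runif(1, 300, 3000), b = runif(1, 300, 3000),
         c = runif(1, 1e-4, 0.2), k = runif(1, 1e-3, 0.6),
         y = runif(1, 0.5, 40), z = runif(1, 0.5, 25),
         g = runif(1, 5, 200),
         j = runif(1, 0.01, 0.99) * consts$Stot / consts$Btot)
  p[model_spec(model_name)$param_names]
}
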