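#' Assemble a kinetics titration dataset
#'
#' @param substrate_conc Substrate concentrations (uM), >= 5 distinct values.
#' @param initial_velocity Initial velocities (arbitrary units/min or
#'   uM/min), same length.
#' @return A `kinetic_dataset` data frame.
#' @export
kinetic_dataset <- function(substrate_conc, initial_velocity) {
  if (length(substrate_conc) != length(initial_velocity))
    stop("substrate_conc and initial_velocity must have equal length")
  if (any(substrate_conc < 0)) stop("substrate concentrations must be >= 0")
  if (length(unique(substrate_conc)) < 5L)
    stop("need >= 5 distinct substrate concentrations")
  out <- data.frame(substrate_conc = substrate_conc,
                    initial_velocity = initial_velocity)
  class(out) <- c("kinetic_dataset", "data.frame")
  out
}

#' Read a kinetics dataset from TSV
#'
#' Expects columns `substrate_conc` and `initial_velocity`.
#'
#' @param path TSV path.
#' @return A `kinetic_dataset`.
#' @export
read_kinetics_tsv <- function(path) {
  df <- utils::read.delim(path)
  kinetic_dataset(df$substrate_conc, df$initial_velocity)
}

#' Fit the Hill equation to an initial-velocity titration
#'
#' Least-squares fit of `v = Vmax * S^n / (K^n + S^n)` by
#' Levenberg-Marquardt with multi-start initialization: `K` started at
#' quantiles of the substrate range and the Hill coefficient `n` at several
#' plausible values, keeping the best of the converged starts. At `S = K`
#' the fitted curve is exactly `Vmax / 2`.
#'
#' @param data A [kinetic_dataset()].
#' @param n_fixed Optionally fix the Hill coefficient (e.g. `1` for a
#'   hyperbolic Michaelis-Menten fit); default NULL floats it.
#' @param n_starts Minimum number of starting points (default 9).
#' @param seed Integer seed (start jitter is deterministic given it).
#' @return A `kinetic_fit` list: `Vmax`, `K`, `n`, `residual_norm`,
#'   `converged`, `n_starts_converged`, and NULL placeholders for
#'   `enzyme_conc`, `kcat`, `kcat_over_K`.
#' @export
fit_hill <- function(data, n_fixed = NULL, n_starts = 9L, seed = 1L) {
  stopifnot(inherits(data, "kinetic_dataset"))
  v <- data$initial_velocity
  S <- data$substrate_conc
  if (all(v == 0)) stop("all velocities are zero; nothing to fit")
  set.seed(seed)

  K_grid <- stats::quantile(S[S > 0], c(0.1, 0.25, 0.5, 0.75, 0.9),
                            names = FALSE)
  n_grid <- if (is.null(n_fixed)) c(0.7, 1, 1.5, 2) else n_fixed
  starts <- expand.grid(K = unique(K_grid), n = n_grid)
  if (nrow(starts) < n_starts)
    starts <- starts[rep(seq_len(nrow(starts)),
                         length.out = n_starts), , drop = FALSE]
  Vmax0 <- max(v) * 1.05

  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch({
      if (is.null(n_fixed)) {
        minpack.lm::nlsLM(
          initial_velocity ~ Vmax * substrate_conc^n /
            (K^n + substrate_conc^n),
          data = data,
          start = list(Vmax = Vmax0, K = starts$K[i], n = starts$n[i]),
          lower = c(Vmax = 1e-12, K = 1e-12, n = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        n <- n_fixed
        minpack.lm::nlsLM(
          initial_velocity ~ Vmax * substrate_conc^n /
            (K^n + substrate_conc^n),
          data = data,
          start = list(Vmax = Vmax0, K = starts$K[i]),
          lower = c(Vmax = 1e-12, K = 1e-12),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(Vmax = NA_real_, K = NA_real_,
                          n = n_fixed %||% NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          n_starts_converged = 0L, enzyme_conc = NULL,
                          kcat = NULL, kcat_over_K = NULL),
                     class = "kinetic_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(Vmax = unname(cf["Vmax"]), K = unname(cf["K"]),
                 n = if (is.null(n_fixed)) unname(cf["n"]) else n_fixed,
                 residual_norm = sqrt(best$rss), converged = TRUE,
                 n_starts_converged = n_conv,
                 enzyme_conc = NULL, kcat = NULL, kcat_over_K = NULL),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> Vmax = %.4g, K = %.4g uM, n = %.3g (%s)\n",
              x$Vmax, x$K, x$n,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$kcat))
    cat(sprintf("  kcat = %.4g /s, kcat/K = %.4g /uM/s (enzyme %.4g uM)\n",
                x$kcat, x$kcat_over_K, x$enzyme_conc))
  invisible(x)
}

#' Predict velocities from a Hill fit
#'
#' @param object A `kinetic_fit`.
#' @param newdata Substrate concentrations (uM).
#' @param ... Unused.
#' @return Predicted initial velocities.
#' @export
predict.kinetic_fit <- function(object, newdata, ...) {
  S <- if (is.data.frame(newdata)) newdata$substrate_conc else newdata
  object$Vmax * S^object$n / (object$K^object$n + S^object$n)
}

#' Active enzyme concentration by active-site titration
#'
#' Residual activity against the concentration of an irreversible
#' active-site inhibitor declines linearly until the enzyme is fully
#' titrated; the active enzyme concentration is the x-intercept of the
#' declining regime. Points after activity first reaches (near) zero are
#' excluded from the line fit.
#'
#' @param inhibitor_conc Inhibitor concentrations (uM), increasing.
#' @param residual_activity Observed activities (any consistent unit);
#'   must be non-increasing within `monotone_tol`.
#' @param monotone_tol Tolerated relative increase between consecutive
#'   points (default 0.05 of the maximal activity).
#' @return Enzyme concentration (uM).
#' @export
active_site_titration <- function(inhibitor_conc, residual_activity,
                                  monotone_tol = 0.05) {
  stopifnot(length(inhibitor_conc) == length(residual_activity))
  o <- order(inhibitor_conc)
  x <- inhibitor_conc[o]
  y <- residual_activity[o]
  if (length(x) < 3L) stop("need >= 3 titration points")
  amax <- max(y)
  if (any(diff(y) > monotone_tol * amax))
    stop("residual activity is not non-increasing in inhibitor ",
         "concentration (beyond tolerance)")
  # declining regime: up to and including the first (near-)zero point
  zero <- which(y <= 1e-9 * amax)
  last <- if (length(zero)) zero[1L] else length(x)
  use <- seq_len(max(3L, last))
  fit <- stats::lm(y[use] ~ x[use])
  slope <- stats::coef(fit)[2L]
  if (!is.finite(slope) || slope >= 0)
    stop("titration line has non-negative slope; cannot locate intercept")
  unname(-stats::coef(fit)[1L] / slope)
}

#' Derive catalytic constants from a Hill fit
#'
#' `kcat = Vmax / [E]` and the catalytic efficiency `kcat / K`. Vmax must be
#' in concentration/time units consistent with the enzyme concentration for
#' kcat to be a true turnover number; unit conversion factors are the
#' caller's responsibility.
#'
#' @param fit A `kinetic_fit`.
#' @param enzyme_conc Active enzyme concentration (uM), > 0 (e.g. from
#'   [active_site_titration()]).
#' @return The fit with `enzyme_conc`, `kcat`, `kcat_over_K` filled in.
#' @export
derive_catalytic_constants <- function(fit, enzyme_conc) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (enzyme_conc <= 0) stop("enzyme_conc must be > 0")
  fit$enzyme_conc <- enzyme_conc
  fit$kcat <- fit$Vmax / enzyme_conc
  fit$kcat_over_K <- fit$kcat / fit$K
  fit
}
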