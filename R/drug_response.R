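# Dose-response summarisation: IC50 by four-parameter logistic fit with a
# LOESS-inversion fallback for curves too shallow to fit, and panel Z-scores
# of IC50s on the (natural-) log scale with the geometric mean as centre.

.check_dose_response <- function(dr) {
  stopifnot(is.data.frame(dr),
            all(c("concentration_uM", "surviving_fraction") %in% names(dr)))
  if (any(dr$concentration_uM <= 0)) stop("concentrations must be positive")
  if (any(dr$surviving_fraction < 0)) {
    stop("surviving fractions must be non-negative")
  }
  if (length(unique(dr$concentration_uM)) < 4) {
    stop("need >= 4 distinct concentrations")
  }
  dr[order(dr$concentration_uM), , drop = FALSE]
}

.non_sigmoid <- function(msg) {
  stop(structure(class = c("non_sigmoid_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' IC50 by four-parameter logistic fit
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (x - log10(ic50))))`
#' on `x = log10(concentration)`, via Levenberg-Marquardt.  The IC50 is the
#' fitted midpoint and the error is its standard error (delta method from
#' the log10-midpoint parameter).
#'
#' @param dr Data frame with `concentration_uM` (positive) and
#'   `surviving_fraction`; at least 4 distinct concentrations that span the
#'   half-maximal response.
#' @return List (`ic50_estimate`): `ic50` (uM), `error` (uM), `method`
#'   (`"sigmoid-fit"`).
#' @seealso [loess_ic50()] for the fallback used when no sigmoid is
#'   resolvable.
#' @export
fit_sigmoid_ic50 <- function(dr) {
  dr <- .check_dose_response(dr)
  x <- log10(dr$concentration_uM)
  y <- dr$surviving_fraction
  if (min(y) > 0.5 * max(y)) {
    .non_sigmoid("response never falls below half its maximum")
  }
  half <- (max(y) + min(y)) / 2
  start <- list(
    top = max(y), bottom = min(y),
    logic50 = x[which.min(abs(y - half))], hill = 1
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (x - logic50))),
      start = start,
      lower = c(top = -Inf, bottom = -Inf, logic50 = min(x) - 2,
                hill = 0.05),
      upper = c(top = Inf, bottom = Inf, logic50 = max(x) + 2, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) .non_sigmoid("logistic fit failed to converge")
  co <- stats::coef(fit)
  ic50 <- 10^co[["logic50"]]
  se_log <- tryCatch(summary(fit)$coefficients["logic50", "Std. Error"],
                     error = function(e) NA_real_)
  if (!is.finite(se_log)) se_log <- 0
  structure(
    list(ic50 = ic50, error = log(10) * ic50 * se_log,
         method = "sigmoid-fit"),
    class = "ic50_estimate"
  )
}

#' IC50 by LOESS inversion
#'
#' Fits a local linear regression (tricube weights) of surviving fraction on
#' log10 concentration, evaluates it on a 1,000-point log-spaced grid over
#' the tested range, and reports the first concentration at which the fitted
#' curve reaches surviving fraction 0.5.  A 95% prediction interval
#' (residual variance plus pointwise fit variance, t quantile at n - 2 df)
#' is inverted at the crossing: the error is half the width, in
#' concentration units, between where the two interval bounds cross 0.5.
#'
#' @param dr Data frame with `concentration_uM` and `surviving_fraction`.
#' @param span LOESS span.  Default 1.
#' @param level Fraction of the starting population defining the IC50.
#'   Default 0.5.
#' @param grid_n Grid resolution.  Default 1000.
#' @return List (`ic50_estimate`): `ic50` (uM), `error` (uM), `method`
#'   (`"loess-inversion"`).
#' @export
loess_ic50 <- function(dr, span = 1, level = 0.5, grid_n = 1000) {
  dr <- .check_dose_response(dr)
  x <- log10(dr$concentration_uM)
  y <- dr$surviving_fraction
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = grid_n)
  pred <- stats::predict(fit, newdata = data.frame(x = grid), se = TRUE)
  first_crossing <- function(curve) {
    i <- which(curve <= level)
    if (length(i) == 0) NA_real_ else 10^grid[min(i)]
  }
  ic50 <- first_crossing(pred$fit)
  if (is.na(ic50)) {
    stop(structure(class = c("no_crossing_error", "error", "condition"),
                   list(message = paste0(
                     "fitted curve never reaches surviving fraction ", level,
                     " within the tested range"), call = sys.call())))
  }
  # Prediction interval: spread of a new observation about the local fit.
  sd_pred <- sqrt(pred$se.fit^2 + fit$s^2)
  tq <- stats::qt(0.975, df = max(1, length(y) - 2))
  lower_cross <- first_crossing(pred$fit - tq * sd_pred) # crosses earlier
  upper_cross <- first_crossing(pred$fit + tq * sd_pred) # crosses later
  if (is.na(lower_cross)) lower_cross <- 10^grid[1]
  if (is.na(upper_cross)) upper_cross <- 10^grid[grid_n]
  structure(
    list(ic50 = ic50, error = (upper_cross - lower_cross) / 2,
         method = "loess-inversion"),
    class = "ic50_estimate"
  )
}

#' IC50 with automatic fallback
#'
#' Tries the four-parameter logistic fit first and falls back to LOESS
#' inversion when the response is too shallow to resolve a sigmoid.
#'
#' @inheritParams fit_sigmoid_ic50
#' @param span LOESS span for the fallback.  Default 1.
#' @return An `ic50_estimate`; `method` records which route produced it.
#' @export
estimate_ic50 <- function(dr, span = 1) {
  tryCatch(fit_sigmoid_ic50(dr),
           non_sigmoid_error = function(e) loess_ic50(dr, span = span))
}

#' @export
print.ic50_estimate <- function(x, ...) {
  cat(sprintf("IC50 = %.4g uM +/- %.3g (%s)\n", x$ic50, x$error, x$method))
  invisible(x)
}

#' Panel Z-scores of drug sensitivity
#'
#' Standardises each cell line's IC50 against the panel on the natural-log
#' scale: `z = (ln IC50 - ln GM) / sd(ln IC50)`, where GM is the panel's
#' geometric-mean IC50 and the sd is the sample standard deviation (n - 1)
#' of the log IC50s.  A line is called sensitive when `z <= cut` (inclusive,
#' default -1.5).  External panel statistics (e.g. from a large reference
#' panel) may be supplied instead of the in-sample ones.  A raw-scale
#' variant — subtract the geometric mean from the raw IC50 and divide by the
#' raw-scale sd — is available behind `log_scale = FALSE`; the log-scale
#' form is the default because only it makes the geometric-mean centring
#' self-consistent.
#'
#' @param ic50s Named numeric vector (cell line -> IC50, uM) or data frame
#'   with `cell_line` and `ic50`.
#' @param drug Drug name recorded in the output.  Default `""`.
#' @param panel_stats Optional list with `mean_ln` and `sd_ln` (log-scale)
#'   or `gm` and `sd` (raw scale) from an external panel.
#' @param cut Sensitivity cut on z, inclusive.  Default -1.5.
#' @param log_scale Standardise on the log scale.  Default TRUE.
#' @return Data frame `cell_line`, `drug`, `ic50`, `z`, `sensitive`.
#' @export
drug_zscores <- function(ic50s, drug = "", panel_stats = NULL, cut = -1.5,
                         log_scale = TRUE) {
  if (is.data.frame(ic50s)) {
    cl <- ic50s$cell_line
    v <- ic50s$ic50
  } else {
    cl <- names(ic50s)
    v <- as.numeric(ic50s)
    if (is.null(cl)) stop("ic50s must be named or a data frame")
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("IC50s must be finite and positive")
  }
  if (is.null(panel_stats) && length(v) < 2) {
    stop("need >= 2 cell lines when no external panel statistics are given")
  }
  if (log_scale) {
    lv <- log(v)
    centre <- if (!is.null(panel_stats)) panel_stats$mean_ln else mean(lv)
    spread <- if (!is.null(panel_stats)) panel_stats$sd_ln else stats::sd(lv)
    z <- (lv - centre) / spread
  } else {
    gm <- if (!is.null(panel_stats)) panel_stats$gm else exp(mean(log(v)))
    spread <- if (!is.null(panel_stats)) panel_stats$sd else stats::sd(v)
    z <- (v - gm) / spread
  }
  if (!is.finite(spread) || spread <= 0) {
    z <- rep(0, length(v))   # all IC50s equal: no line deviates
  }
  data.frame(cell_line = cl, drug = drug, ic50 = v, z = z,
             sensitive = z <= cut, stringsAsFactors = FALSE)
}

#' Join drug sensitivity with gene essentiality across cell lines
#'
#' Inner-joins a drug's per-line Z-scores with per-line gene-effect hit
#' calls for one gene and counts concordant lines (hit status equals
#' sensitivity call).
#'
#' @param zscores Data frame from [drug_zscores()].
#' @param gene_effects Data frame with `cell_line`, a score column (`ceres`
#'   or `quant_log`) and `is_hit`.
#' @return Data frame `cell_line`, `z`, `effect`, `is_hit`, `sensitive`,
#'   with attributes `concordance` (count) and `n` (joined lines).
#' @export
essentiality_vs_sensitivity <- function(zscores, gene_effects) {
  stopifnot(is.data.frame(zscores), is.data.frame(gene_effects))
  shared <- intersect(zscores$cell_line, gene_effects$cell_line)
  if (length(shared) == 0) stop("no shared cell lines between the two tables")
  iz <- match(shared, zscores$cell_line)
  ie <- match(shared, gene_effects$cell_line)
  eff_col <- intersect(c("ceres", "quant_log"), names(gene_effects))[1]
  if (is.na(eff_col)) stop("gene_effects needs a 'ceres' or 'quant_log' column")
  out <- data.frame(
    cell_line = shared,
    z = zscores$z[iz],
    effect = gene_effects[[eff_col]][ie],
    is_hit = gene_effects$is_hit[ie],
    sensitive = zscores$sensitive[iz],
    stringsAsFactors = FALSE
  )
  attr(out, "concordance") <- sum(out$is_hit == out$sensitive)
  attr(out, "n") <- nrow(out)
  out
}
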