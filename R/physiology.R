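# Physiology readouts: von Frey mechanical sensitivity curves with AUC, and
# wire-myography normalization with four-parameter logistic (4PL) EC50 fits.

#' Default von Frey filament set (grams)
#'
#' The standard descending set applied five times each: 4.00, 2.00, 1.00,
#' 0.40 and 0.02 g.
#' @return Numeric vector of filament strengths in grams.
#' @export
vonfrey_filaments <- function() c(4.00, 2.00, 1.00, 0.40, 0.02)

#' Validate a von Frey trial table
#'
#' @param table Data frame with columns `animal`, `filament_g` (> 0),
#'   `trial` and `response` (logical or 0/1: immediate withdrawal or licking
#'   within 1 s).
#' @param trials_expected Trials required per (animal, filament); default 5.
#' @return The table, invisibly; errors list the offending filament.
#' @export
validate_vonfrey_table <- function(table, trials_expected = 5L) {
  req <- c("animal", "filament_g", "trial", "response")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("missing von Frey column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(table$filament_g <= 0)) stop("filament strengths must be > 0", call. = FALSE)
  if (!all(table$response %in% c(0, 1, TRUE, FALSE)))
    stop("`response` must be boolean (0/1)", call. = FALSE)
  cnt <- table(table$animal, table$filament_g)
  if (!is.null(trials_expected) && any(cnt != 0 & cnt != trials_expected)) {
    bad <- which(cnt != 0 & cnt != trials_expected, arr.ind = TRUE)
    stop(sprintf("wrong trial count for animal '%s', filament %s g (expected %d)",
                 rownames(cnt)[bad[1L, 1L]], colnames(cnt)[bad[1L, 2L]],
                 trials_expected), call. = FALSE)
  }
  invisible(table)
}

#' Per-filament response fractions for one animal
#'
#' @param table Von Frey trial table for a single animal (see
#'   [validate_vonfrey_table()]).
#' @param trials_expected Trials required per filament (default 5).
#' @return A `sensitivity_curve`: data frame ordered by ascending filament
#'   strength with columns `filament_g`, `n_trials`, `fraction`.
#' @export
response_curve <- function(table, trials_expected = 5L) {
  validate_vonfrey_table(table, trials_expected)
  if (length(unique(table$animal)) != 1L)
    stop("`response_curve` expects a single animal; split the table first", call. = FALSE)
  resp <- as.numeric(table$response)
  agg <- aggregate(resp, by = list(filament_g = table$filament_g), FUN = mean)
  n <- aggregate(resp, by = list(filament_g = table$filament_g), FUN = length)
  out <- data.frame(filament_g = agg$filament_g, n_trials = n$x, fraction = agg$x)
  out <- out[order(out$filament_g), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_curve", "data.frame"))
}

#' Area under a sensitivity curve
#'
#' Trapezoidal integral of response fraction against filament strength on a
#' linear gram axis (ascending). Units: gram x fraction. A constant-1 curve
#' over 0.02--4.00 g therefore integrates to 3.98.
#'
#' @param curve A `sensitivity_curve` from [response_curve()], or any data
#'   frame with `filament_g` and `fraction`.
#' @param log_axis Integrate against `log10(filament_g)` instead (off by
#'   default).
#' @return The AUC.
#' @export
vonfrey_auc <- function(curve, log_axis = FALSE) {
  if (nrow(curve) < 2L)
    stop("AUC needs at least two filaments", call. = FALSE)
  o <- order(curve$filament_g)
  x <- curve$filament_g[o]
  if (log_axis) x <- log10(x)
  y <- curve$fraction[o]
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Normalize contraction peaks to the maximal KCl contraction
#'
#' @param trace_peaks Numeric vector of peak forces, one per dose.
#' @param kcl_max Maximal KCl-induced contraction force (> 0).
#' @param doses Optional molar doses (ascending) to attach.
#' @return A [dose_response()] when `doses` is given, else the percent vector
#'   `100 * peak / kcl_max`.
#' @export
normalize_contraction <- function(trace_peaks, kcl_max, doses = NULL) {
  if (kcl_max <= 0) stop("`kcl_max` must be > 0", call. = FALSE)
  pct <- 100 * trace_peaks / kcl_max
  if (is.null(doses)) pct else dose_response(doses, pct)
}

#' Relaxation as a percentage of pre-contraction
#'
#' `relaxation% = 100 * (precontraction - force) / precontraction`; full
#' return to baseline is 100%, no change is 0%.
#'
#' @param trace Numeric vector of forces, one per dose.
#' @param precontraction Pre-contraction force (> 0).
#' @param doses Optional molar doses (ascending) to attach.
#' @return A [dose_response()] when `doses` is given, else the percent vector.
#' @export
normalize_relaxation <- function(trace, precontraction, doses = NULL) {
  if (precontraction <= 0) stop("`precontraction` must be > 0", call. = FALSE)
  pct <- 100 * (precontraction - trace) / precontraction
  if (is.null(doses)) pct else dose_response(doses, pct)
}

#' Dose-response container
#'
#' @param doses Strictly increasing positive molar doses.
#' @param responses Responses (e.g. % of KCl max, or % relaxation).
#' @return Object of class `dose_response`.
#' @export
dose_response <- function(doses, responses) {
  if (length(doses) != length(responses))
    stop("`doses` and `responses` must have the same length", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing", call. = FALSE)
  structure(list(dose = as.numeric(doses), response = as.numeric(responses)),
            class = "dose_response")
}

#' Default molar dose ladder spanning 2 nM to 10 uM
#'
#' Ten log-spaced doses across the conventional agonist range.
#' @return Numeric vector of molar doses.
#' @export
default_dose_ladder <- function() 10^seq(log10(2e-9), log10(1e-5), length.out = 10)

#' Fit a four-parameter logistic (4PL) and report the EC50
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (ec50 / dose)^hill)`
#' on the log-dose axis. Initialization is pinned for determinism: bottom and
#' top from the response extrema, EC50 from the dose whose response is
#' closest to the half-range, Hill slope +/-1 by the sign of the trend; EC50
#' is bounded within `[min(dose)/10, max(dose)*10]`. The fit is canonicalized
#' so `bottom <= top` (swapping flips the Hill sign, leaving the curve
#' unchanged).
#'
#' @param dr A [dose_response()] with at least 4 doses spanning the
#'   transition.
#' @return An `ec50_fit` list: `bottom`, `top`, `hill_slope`, `ec50` (molar),
#'   `rss`, `fitted`, `converged`.
#' @export
fit_ec50 <- function(dr) {
  if (!inherits(dr, "dose_response")) stop("`dr` must be a dose_response", call. = FALSE)
  d <- dr$dose; y <- dr$response
  if (length(d) < 4L) stop("EC50 fit needs at least 4 doses", call. = FALSE)
  rng <- max(y) - min(y)
  if (rng < 1e-8 * max(1, max(abs(y))))
    stop("flat dose-response: EC50 undefined (response range ~ 0)", call. = FALSE)
  ld <- log(d)
  bottom0 <- min(y); top0 <- max(y)
  half <- (bottom0 + top0) / 2
  lec0 <- ld[which.min(abs(y - half))]
  hill0 <- if (suppressWarnings(stats::cor(ld, y)) >= 0) 1 else -1
  lo <- c(bottom = min(y) - 2 * rng, top = min(y) - 2 * rng,
          lec = log(min(d) / 10), hill = -20)
  hi <- c(bottom = max(y) + 2 * rng, top = max(y) + 2 * rng,
          lec = log(max(d) * 10), hill = 20)
  f4pl <- function(p) p[1L] + (p[2L] - p[1L]) / (1 + exp(p[4L] * (p[3L] - ld)))
  rssfun <- function(p) sum((y - f4pl(p))^2)
  p0 <- c(bottom = bottom0, top = top0, lec = lec0, hill = hill0)
  opt <- stats::optim(p0, rssfun, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 500L, factr = 1e4))
  # polish with Gauss-Newton (nls) from the optim solution when possible
  p <- opt$par
  fit <- tryCatch({
    df <- data.frame(ld = ld, y = y)
    nl <- stats::nls(y ~ bottom + (top - bottom) / (1 + exp(hill * (lec - ld))),
                     data = df,
                     start = as.list(p), algorithm = "port",
                     lower = lo, upper = hi,
                     control = stats::nls.control(maxiter = 200L, warnOnly = TRUE))
    cf <- coef(nl)
    rss <- sum(resid(nl)^2)
    if (rss <= rssfun(p)) list(par = cf, rss = rss) else list(par = p, rss = rssfun(p))
  }, error = function(e) list(par = p, rss = rssfun(p)))
  p <- fit$par
  flat_rss <- sum((y - mean(y))^2)
  if (!is.finite(fit$rss) || fit$rss > flat_rss + 1e-9)
    stop("EC50 fit failed: no improvement over the flat-mean model", call. = FALSE)
  bottom <- unname(p["bottom"]); top <- unname(p["top"])
  hill <- unname(p["hill"]); ec50 <- exp(unname(p["lec"]))
  if (bottom > top) { tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill }
  structure(list(bottom = bottom, top = top, hill_slope = hill, ec50 = ec50,
                 rss = fit$rss,
                 fitted = bottom + (top - bottom) / (1 + (ec50 / d)^hill),
                 converged = TRUE),
            class = "ec50_fit")
}
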