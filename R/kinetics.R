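# Substrate-inhibition Michaelis-Menten kinetics for esterase initial-rate
# data. The uncompetitive substrate-inhibition law
#
#   v = Vmax * S / (Km + S * (1 + S / Ki))
#
# reduces to plain Michaelis-Menten as Ki -> Inf and has a single interior
# rate maximum at S* = sqrt(Km * Ki).

#' Construct a substrate-inhibition kinetic model
#'
#' @param Km Michaelis constant (mM).
#' @param Ki Substrate-inhibition constant (mM).
#' @param Vmax Maximal (uninhibited) rate; units set by the assay. Supply
#'   either `Vmax` directly or `kcat` plus `E_total`.
#' @param kcat Turnover number (s^-1), used with `E_total` when `Vmax` is not
#'   given (`Vmax = kcat * E_total`).
#' @param E_total Molar enzyme amount in units consistent with `Vmax`, so
#'   that `Vmax / E_total` is in s^-1.
#' @return An `si_model` list with fields `Vmax`, `Km`, `Ki`, `E_total`,
#'   `kcat`.
#' @examples
#' si_model(Km = 2.29, Ki = 14, kcat = 0.89, E_total = 1)
#' @export
si_model <- function(Km, Ki, Vmax = NULL, kcat = NULL, E_total = 1) {
  if (is.null(Vmax)) {
    if (is.null(kcat)) stop("supply either Vmax or kcat")
    Vmax <- kcat * E_total
  }
  if (is.null(kcat)) kcat <- Vmax / E_total
  for (nm in c("Vmax", "Km", "Ki", "E_total"))
    if (!is.numeric(get(nm)) || get(nm) <= 0)
      stop(nm, " must be a positive number")
  structure(list(Vmax = Vmax, Km = Km, Ki = Ki, E_total = E_total,
                 kcat = kcat),
            class = "si_model")
}

#' @export
print.si_model <- function(x, ...) {
  cat(sprintf(
    "<substrate-inhibition model> Vmax %.4g  Km %.4g mM  Ki %.4g mM  kcat %.4g /s\n",
    x$Vmax, x$Km, x$Ki, x$kcat))
  cat(sprintf("  optimum S* = sqrt(Km*Ki) = %.4g mM\n", sqrt(x$Km * x$Ki)))
  invisible(x)
}

#' Substrate-inhibition rate law
#'
#' @param S Substrate concentration(s), mM; must be positive.
#' @param Vmax,Km,Ki Positive model parameters (see [si_model()]).
#' @return Initial rate(s) `v` at each `S`.
#' @examples
#' rate_si(2.29, Vmax = 1, Km = 2.29, Ki = 14)  # 0.4622
#' @export
rate_si <- function(S, Vmax, Km, Ki) {
  if (any(!is.finite(S)) || any(S <= 0)) stop("S must be positive")
  for (nm in c("Vmax", "Km", "Ki"))
    if (!is.numeric(get(nm)) || length(get(nm)) != 1 || get(nm) <= 0)
      stop(nm, " must be a positive number")
  Vmax * S / (Km + S * (1 + S / Ki))
}

#' Plain Michaelis-Menten rate law
#'
#' @inheritParams rate_si
#' @return Initial rate(s) `v` at each `S`.
#' @export
rate_mm <- function(S, Vmax, Km) {
  if (any(!is.finite(S)) || any(S <= 0)) stop("S must be positive")
  Vmax * S / (Km + S)
}

.rate_data <- function(data) {
  if (!is.data.frame(data) || ncol(data) < 2)
    stop("rate data must be a data frame with substrate and rate columns")
  nm <- names(data)
  s_col <- intersect(c("S", "S_mM", "substrate"), nm)[1]
  v_col <- intersect(c("v0", "v", "rate"), nm)[1]
  d <- data.frame(S = data[[if (is.na(s_col)) 1L else s_col]],
                  v0 = data[[if (is.na(v_col)) 2L else v_col]])
  if (any(d$S <= 0)) stop("substrate concentrations must be positive")
  if (any(d$v0 < 0)) stop("rates must be non-negative")
  d
}

.start_heuristic <- function(d, ki0_factor = 10) {
  vmax0 <- 1.5 * max(d$v0)
  half <- vmax0 / 2
  ord <- order(d$S)
  km0 <- d$S[ord][which.min(abs(d$v0[ord] - half))]
  if (km0 <= 0) km0 <- stats::median(d$S)
  list(Vmax = vmax0, Km = km0, Ki = ki0_factor * max(d$S))
}

#' Fit the substrate-inhibition model to initial-rate data
#'
#' Weighted nonlinear least squares via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). The default relative weighting (1/v^2) treats the
#' measurement error of enzymatic initial rates as proportional to the rate,
#' the usual situation for absorbance-derived rates spanning an order of
#' magnitude. Standard errors come from the local curvature of the weighted
#' objective at the optimum. `kcat` is derived as `Vmax / E_total`; supply
#' `E_total` in units making that ratio s^-1.
#'
#' Fitted `Ki` running into `ki_max` (the "effectively Michaelis-Menten"
#' sentinel) is flagged via `effectively_mm`.
#'
#' @param data Data frame of positive substrate concentrations and
#'   non-negative rates (columns `S`/`S_mM` and `v0`/`v`, or the first two
#'   columns).
#' @param E_total Molar enzyme amount linking `Vmax` to `kcat`; `NA` kcat if
#'   omitted.
#' @param weighting `"relative"` (1/v^2, default) or `"none"`.
#' @param start Optional named list (`Vmax`, `Km`, `Ki`) overriding the
#'   start heuristic (`Vmax0 = 1.5 max v`; `Km0 = S` nearest half of `Vmax0`;
#'   `Ki0 = 10 max S`).
#' @param ki_max Upper bound on `Ki` (mM).
#' @return An `si_fit` list: `model` (an [si_model()] when converged),
#'   `parameters`, `std_errors`, `converged`, `effectively_mm`, `rss`, `n`,
#'   `residuals`, `data`, `fit` (the underlying `nls` object or `NULL`).
#' @examples
#' d <- generate_kinetics(si_model(Km = 2.29, Ki = 14, kcat = 0.89),
#'                        S = seq(0.25, 10, length.out = 40))
#' fit_si(d, E_total = 1)
#' @export
fit_si <- function(data, E_total = NULL, weighting = c("relative", "none"),
                   start = NULL, ki_max = 1e6) {
  weighting <- match.arg(weighting)
  d <- .rate_data(data)
  if (length(unique(d$S)) < 4)
    stop("at least 4 distinct substrate concentrations are required ",
         "(3 parameters + 1)")
  if (stats::sd(d$v0) == 0) {
    return(structure(list(
      model = NULL,
      parameters = c(Vmax = NA_real_, Km = NA_real_, Ki = NA_real_,
                     kcat = NA_real_),
      std_errors = c(Vmax = NA_real_, Km = NA_real_, Ki = NA_real_),
      converged = FALSE, effectively_mm = NA,
      message = "degenerate input: rates constant across S (unidentifiable)",
      rss = NA_real_, n = nrow(d), residuals = rep(NA_real_, nrow(d)),
      data = d, fit = NULL), class = "si_fit"))
  }
  if (is.null(start)) start <- .start_heuristic(d)
  w <- if (weighting == "relative") 1 / pmax(d$v0, 1e-12)^2 else rep(1, nrow(d))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v0 ~ Vmax * S / (Km + S * (1 + S / Ki)), data = d, weights = w,
      start = start, lower = c(1e-12, 1e-12, 1e-12), upper = c(Inf, Inf, ki_max),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error") || !isTRUE(fit$convInfo$isConv)) {
    return(structure(list(
      model = NULL,
      parameters = c(Vmax = NA_real_, Km = NA_real_, Ki = NA_real_,
                     kcat = NA_real_),
      std_errors = c(Vmax = NA_real_, Km = NA_real_, Ki = NA_real_),
      converged = FALSE, effectively_mm = NA,
      message = if (inherits(fit, "error")) conditionMessage(fit)
                else "optimizer did not converge",
      rss = NA_real_, n = nrow(d), residuals = rep(NA_real_, nrow(d)),
      data = d, fit = NULL), class = "si_fit"))
  }
  p <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kcat <- if (is.null(E_total)) NA_real_ else unname(p["Vmax"]) / E_total
  structure(list(
    model = si_model(Km = unname(p["Km"]), Ki = unname(p["Ki"]),
                     Vmax = unname(p["Vmax"]),
                     E_total = if (is.null(E_total)) 1 else E_total),
    parameters = c(Vmax = unname(p["Vmax"]), Km = unname(p["Km"]),
                   Ki = unname(p["Ki"]), kcat = kcat),
    std_errors = setNames(as.numeric(se), c("Vmax", "Km", "Ki")),
    converged = TRUE,
    effectively_mm = unname(p["Ki"]) >= 0.99 * ki_max,
    message = "converged",
    rss = sum(resid(fit)^2), n = nrow(d), residuals = as.numeric(resid(fit)),
    data = d, fit = fit), class = "si_fit")
}

#' @export
print.si_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<substrate-inhibition fit> NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  p <- x$parameters; se <- x$std_errors
  cat("<substrate-inhibition fit>\n")
  cat(sprintf("  Vmax = %.4g +- %.2g\n", p["Vmax"], se["Vmax"]))
  cat(sprintf("  Km   = %.4g +- %.2g mM\n", p["Km"], se["Km"]))
  cat(sprintf("  Ki   = %.4g +- %.2g mM%s\n", p["Ki"], se["Ki"],
              if (isTRUE(x$effectively_mm)) "  [at bound: effectively MM]" else ""))
  if (!is.na(p["kcat"])) cat(sprintf("  kcat = %.4g /s\n", p["kcat"]))
  cat(sprintf("  n = %d, weighted RSS = %.4g\n", x$n, x$rss))
  invisible(x)
}

#' Fit the plain Michaelis-Menten model
#'
#' @inheritParams fit_si
#' @return An `mm_fit` list analogous to [fit_si()]'s result, with
#'   parameters `Vmax`, `Km`, `kcat`.
#' @export
fit_mm <- function(data, E_total = NULL, weighting = c("relative", "none"),
                   start = NULL) {
  weighting <- match.arg(weighting)
  d <- .rate_data(data)
  if (length(unique(d$S)) < 3)
    stop("at least 3 distinct substrate concentrations are required")
  if (is.null(start)) start <- .start_heuristic(d)[c("Vmax", "Km")]
  w <- if (weighting == "relative") 1 / pmax(d$v0, 1e-12)^2 else rep(1, nrow(d))
  fit <- tryCatch(
    minpack.lm::nlsLM(v0 ~ Vmax * S / (Km + S), data = d, weights = w,
                      start = start, lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error") || !isTRUE(fit$convInfo$isConv)) {
    return(structure(list(
      parameters = c(Vmax = NA_real_, Km = NA_real_, kcat = NA_real_),
      std_errors = c(Vmax = NA_real_, Km = NA_real_),
      converged = FALSE,
      message = if (inherits(fit, "error")) conditionMessage(fit)
                else "optimizer did not converge",
      rss = NA_real_, n = nrow(d), data = d, fit = NULL), class = "mm_fit"))
  }
  p <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  kcat <- if (is.null(E_total)) NA_real_ else unname(p["Vmax"]) / E_total
  structure(list(
    parameters = c(Vmax = unname(p["Vmax"]), Km = unname(p["Km"]),
                   kcat = kcat),
    std_errors = setNames(as.numeric(se), c("Vmax", "Km")),
    converged = TRUE, message = "converged",
    rss = sum(resid(fit)^2), n = nrow(d), data = d, fit = fit),
    class = "mm_fit")
}

#' Compare substrate-inhibition against plain Michaelis-Menten
#'
#' Fits both rate laws to the same dataset and reports residual sums of
#' squares, parameter counts, and a small-sample corrected information
#' criterion (AICc, error variance counted as a parameter). To keep nested
#' noise-free fits comparable, residual sums are floored at a tiny
#' data-scaled value so that equal (numerically zero) residuals let the
#' parameter-count penalty decide in favour of the reduced model.
#'
#' @inheritParams fit_si
#' @return A `model_comparison` list: `si`, `mm` (the two fits), `table`
#'   (per-model n, parameters, RSS, AICc), `preferred` (`"SI"` or `"MM"`),
#'   `delta_aicc` (AICc(SI) - AICc(MM)).
#' @export
compare_models <- function(data, E_total = NULL,
                           weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  si <- fit_si(data, E_total = E_total, weighting = weighting)
  mm <- fit_mm(data, E_total = E_total, weighting = weighting)
  if (!si$converged || !mm$converged)
    stop("model comparison requires both fits to converge (SI: ",
         si$message, "; MM: ", mm$message, ")")
  n <- si$n
  floor_rss <- n * (1e-8 * mean(si$data$v0))^2
  aicc <- function(rss, k) {
    rss <- max(rss, floor_rss)
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  a_si <- aicc(si$rss, 4)  # Vmax, Km, Ki + sigma
  a_mm <- aicc(mm$rss, 3)  # Vmax, Km + sigma
  structure(list(
    si = si, mm = mm,
    table = data.frame(model = c("SI", "MM"), n = n, k = c(4L, 3L),
                       rss = c(si$rss, mm$rss), aicc = c(a_si, a_mm)),
    preferred = if (a_si < a_mm) "SI" else "MM",
    delta_aicc = a_si - a_mm), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model comparison> preferred:", x$preferred,
      sprintf("(delta AICc SI-MM = %.2f)\n", x$delta_aicc))
  print(x$table)
  invisible(x)
}

#' Descriptive pH optimum from a measured profile
#'
#' Reports the pH of maximal activity and, when neighbouring points fall
#' within `flat_tol` of the maximum, the flat-top range they span.
#'
#' @param pH,activity Paired measurements.
#' @param flat_tol Relative tolerance defining the flat top (default 5%).
#' @return List with `optimum`, `flat_range`, `is_flat_top`.
#' @export
ph_optimum <- function(pH, activity, flat_tol = 0.05) {
  if (length(pH) != length(activity) || !length(pH))
    stop("pH and activity must be non-empty and the same length")
  top <- max(activity)
  flat <- pH[activity >= (1 - flat_tol) * top]
  list(optimum = pH[which.max(activity)],
       flat_range = range(flat),
       is_flat_top = length(flat) > 1)
}
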