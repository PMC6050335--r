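#' Two-state melting models and van't Hoff thermodynamics
#'
#' UV melting of a short RNA duplex or hairpin is modelled as a two-state
#' folded/unfolded equilibrium characterised by the melting temperature
#' \eqn{T_m} and the van't Hoff enthalpy \eqn{\Delta H}. The folded fraction
#' at temperature \eqn{T} follows from the equilibrium constant
#' \eqn{K = \exp[(1/T_m - 1/T)\,\Delta H / R]}: for a self-complementary
#' hairpin \eqn{f = K/(1+K)}, while for a bimolecular duplex the strand
#' concentration enters and \eqn{f} is the root of a quadratic. Both curves
#' pass through 0.5 exactly at \eqn{T_m}.
#'
#' @param T_K temperature(s) in kelvin.
#' @param Tm melting temperature in kelvin.
#' @param dH van't Hoff enthalpy in kcal/mol (negative for folding).
#' @return Folded fraction in \[0, 1\], vectorised over `T_K`.
#' @examples
#' fraction_folded_hairpin(330, Tm = 330, dH = -45)   # 0.5 at Tm
#' fraction_folded_duplex(c(310, 330, 350), Tm = 330, dH = -40)
#' @name melting-models
NULL

#' @rdname melting-models
#' @export
fraction_folded_duplex <- function(T_K, Tm, dH) {
  check_melt_args(T_K, Tm)
  x <- (1 / Tm - 1 / T_K) * dH / RGAS
  e <- exp(x)
  f <- (1 + 4 * e - sqrt(1 + 8 * e)) / (4 * e)
  # exp overflow (deeply folded) -> f = 1; underflow (melted) -> f = 0
  f[is.infinite(e)] <- 1
  f[e == 0] <- 0
  pmin(pmax(f, 0), 1)
}

#' @rdname melting-models
#' @export
fraction_folded_hairpin <- function(T_K, Tm, dH) {
  check_melt_args(T_K, Tm)
  x <- (1 / Tm - 1 / T_K) * dH / RGAS
  stats::plogis(x)  # overflow-safe logistic
}

check_melt_args <- function(T_K, Tm) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop_domain("temperatures must be positive and finite (kelvin)")
  if (!is.finite(Tm) || Tm <= 0)
    stop_domain("`Tm` must be positive and finite (kelvin)")
}

#' Construct a melting curve object
#'
#' Bundles a temperature grid with the observed signal. Temperatures may be
#' supplied in kelvin or celsius; they are stored in kelvin.
#'
#' @param temperature numeric vector, strictly increasing.
#' @param signal numeric vector, same length: folded fraction or raw
#'   absorbance depending on `signal_kind`.
#' @param signal_kind `"fraction"` or `"absorbance"`.
#' @param ct total strand concentration in mol/L (required for duplex fits).
#' @param unit temperature unit of the input, `"K"` or `"C"`.
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperature, signal, signal_kind = c("fraction", "absorbance"),
                          ct = NULL, unit = c("K", "C")) {
  signal_kind <- match.arg(signal_kind)
  unit <- match.arg(unit)
  if (unit == "C") temperature <- temperature + 273.15
  if (length(temperature) != length(signal))
    stop_domain("temperature and signal must have equal length")
  if (length(temperature) < 8L)
    stop_domain("a melting curve needs at least 8 points")
  if (any(diff(temperature) <= 0))
    stop_domain("temperatures must be strictly increasing")
  if (any(temperature <= 0)) stop_domain("temperatures must be positive kelvin")
  if (!is.null(ct) && (!is.finite(ct) || ct <= 0))
    stop_domain("`ct` must be a positive concentration in mol/L")
  structure(list(temperature = as.numeric(temperature),
                 signal = as.numeric(signal),
                 signal_kind = signal_kind, ct = ct),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> %d points, %.1f-%.1f K, signal = %s\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              x$signal_kind))
  invisible(x)
}

#' Derive entropy and free energy from two-state melting parameters
#'
#' For a hairpin (unimolecular) transition \eqn{\Delta S = \Delta H / T_m};
#' for a bimolecular duplex \eqn{\Delta S = \Delta H / T_m - R \ln(C_T/2)}
#' where \eqn{C_T} is the total strand concentration. In both cases
#' \eqn{\Delta G = \Delta H - T \Delta S} at the evaluation temperature.
#'
#' @param Tm,dH two-state parameters (kelvin, kcal/mol).
#' @param model `"hairpin"` or `"duplex"`.
#' @param ct total strand concentration in mol/L; required iff `model = "duplex"`.
#' @param t_eval evaluation temperature in kelvin (default 310.15 K = 37 C).
#' @return list with `dS` (kcal/mol/K) and `dG` (kcal/mol at `t_eval`).
#' @examples
#' derive_thermo(Tm = 330, dH = -45, model = "hairpin")
#' @export
derive_thermo <- function(Tm, dH, model = c("hairpin", "duplex"), ct = NULL,
                          t_eval = 310.15) {
  model <- match.arg(model)
  if (model == "duplex") {
    if (is.null(ct)) stop_domain("`ct` is required for the duplex model",
                                 "m6aj_argument_error")
    dS <- dH / Tm - RGAS * log(ct / 2)
  } else {
    dS <- dH / Tm
  }
  list(dS = dS, dG = dH - t_eval * dS, t_eval = t_eval)
}

#' Fit a two-state model to a melting curve
#'
#' Nonlinear least-squares fit of \eqn{T_m} and \eqn{\Delta H} (via
#' [minpack.lm::nlsLM]) with a deterministic multi-start strategy: \eqn{T_m}
#' is initialised at the temperature where the signal crosses its midpoint,
#' \eqn{\Delta H} at -40 kcal/mol, and both are perturbed over a 3x3 grid
#' (\eqn{T_m \pm 5} K, \eqn{\Delta H \times \{0.5, 1, 2\}}); the start with
#' the lowest residual sum of squares wins, ties broken by grid order.
#'
#' For raw absorbance data (`baseline = "linear"`) folded and unfolded
#' linear baselines are fitted jointly:
#' \eqn{A(T) = (m_F T + b_F) f(T) + (m_U T + b_U)(1 - f(T))}.
#'
#' @param curve a [melting_curve()].
#' @param model `"hairpin"` or `"duplex"`; the duplex model needs `curve$ct`.
#' @param baseline `"none"` (signal is folded fraction) or `"linear"`.
#' @param t_eval temperature (K) at which the derived dG is reported.
#' @param n_boot parametric bootstrap resamples for parameter uncertainties
#'   (0 = off). Resampling is seeded and deterministic.
#' @param boot_seed seed for the bootstrap stream.
#' @return An object of class `melt_fit`: Tm, dH, dS, dG (at `t_eval`), rss,
#'   baseline coefficients when fitted, and `se` when bootstrapped.
#' @export
fit_melting <- function(curve, model = c("hairpin", "duplex"),
                        baseline = c("none", "linear"), t_eval = 310.15,
                        n_boot = 0, boot_seed = 1L) {
  stopifnot(inherits(curve, "melting_curve"))
  model <- match.arg(model)
  baseline <- match.arg(baseline)
  if (model == "duplex" && is.null(curve$ct))
    stop_domain("duplex fits need `ct` on the melting curve", "m6aj_argument_error")
  if (curve$signal_kind == "fraction") {
    if (any(curve$signal < -0.05 | curve$signal > 1.05))
      stop_domain("folded-fraction signal outside [-0.05, 1.05]",
                  "m6aj_validation_error")
  } else if (baseline != "linear") {
    stop_domain("absorbance signals require baseline = \"linear\" or pre-normalisation",
                "m6aj_argument_error")
  }

  TT <- curve$temperature
  y <- curve$signal
  ffun <- if (model == "hairpin") fraction_folded_hairpin else fraction_folded_duplex

  # midpoint-crossing initial Tm
  mid <- (max(y) + min(y)) / 2
  Tm0 <- TT[which.min(abs(y - mid))]
  starts <- expand.grid(Tm = Tm0 + c(-5, 0, 5), dH = -40 * c(0.5, 1, 2))

  best <- NULL
  best_rss <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch({
      if (baseline == "none") {
        minpack.lm::nlsLM(y ~ ffun(TT, Tm, dH),
                          start = list(Tm = starts$Tm[s], dH = starts$dH[s]),
                          lower = c(Tm = 100, dH = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        # joint linear baselines; initialise from the 15% tails
        k <- max(2L, round(length(TT) * 0.15))
        lo <- stats::lm(y[seq_len(k)] ~ TT[seq_len(k)])
        hi_i <- seq(length(TT) - k + 1L, length(TT))
        hi <- stats::lm(y[hi_i] ~ TT[hi_i])
        # folded baseline = low-T end, unfolded = high-T end
        minpack.lm::nlsLM(
          y ~ (bF + mF * TT) * ffun(TT, Tm, dH) + (bU + mU * TT) * (1 - ffun(TT, Tm, dH)),
          start = list(Tm = starts$Tm[s], dH = starts$dH[s],
                       bF = stats::coef(lo)[1], mF = stats::coef(lo)[2],
                       bU = stats::coef(hi)[1], mU = stats::coef(hi)[2]),
          lower = c(Tm = 100, dH = -Inf, bF = -Inf, mF = -Inf, bU = -Inf, mU = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss - 1e-12) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (is.null(best))
    stop(structure(class = c("m6aj_fit_error", "error", "condition"),
                   list(message = sprintf(
                     "melting fit failed to converge from all %d starts", nrow(starts)),
                     call = sys.call())))

  cf <- stats::coef(best)
  th <- derive_thermo(cf[["Tm"]], cf[["dH"]], model = model, ct = curve$ct,
                      t_eval = t_eval)
  out <- structure(list(model = model, Tm = cf[["Tm"]], dH = cf[["dH"]],
                        dS = th$dS, dG = th$dG, t_eval = t_eval,
                        ct = curve$ct, rss = best_rss, baseline = baseline,
                        coef = cf, se = NULL),
                   class = "melt_fit")

  if (n_boot > 0) {
    sigma <- sqrt(best_rss / max(1, length(y) - length(cf)))
    yhat <- stats::fitted(best)
    boot <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- yhat + stats::rnorm(length(yhat), sd = sigma)
        cb <- melting_curve(TT, pmin(pmax(yb, -0.049), 1.049),
                            signal_kind = "fraction", ct = curve$ct)
        fb <- tryCatch(fit_melting(cb, model = model, t_eval = t_eval),
                       error = function(e) NULL)
        if (is.null(fb)) c(NA_real_, NA_real_, NA_real_, NA_real_)
        else c(fb$Tm, fb$dH, fb$dS, fb$dG)
      }, numeric(4))
    })
    out$se <- stats::setNames(apply(boot, 1, stats::sd, na.rm = TRUE),
                              c("Tm", "dH", "dS", "dG"))
  }
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit:%s> Tm = %.2f K, dH = %.2f kcal/mol, dS = %.5f kcal/mol/K, dG(%.2f K) = %.2f kcal/mol (rss %.3g)\n",
              x$model, x$Tm, x$dH, x$dS, x$t_eval, x$dG, x$rss))
  invisible(x)
}

#' Fit replicate melting curves and summarise with replicate scatter
#'
#' Fits each replicate independently and reports the mean parameters with the
#' standard deviation across replicates as the uncertainty (the convention for
#' triplicate UV melts). With fewer than 3 replicates the SD is `NA`; use
#' `fit_melting(n_boot = 500)` for a single-curve bootstrap instead.
#'
#' @param curves list of [melting_curve()] replicates.
#' @inheritParams fit_melting
#' @return list with `mean` and `sd` named vectors (Tm, dH, dS, dG), the
#'   per-replicate `fits`, plus `model` and `t_eval`.
#' @export
fit_melting_replicates <- function(curves, model = c("hairpin", "duplex"),
                                   baseline = c("none", "linear"), t_eval = 310.15) {
  model <- match.arg(model)
  baseline <- match.arg(baseline)
  fits <- lapply(curves, fit_melting, model = model, baseline = baseline,
                 t_eval = t_eval)
  mat <- vapply(fits, function(f) c(Tm = f$Tm, dH = f$dH, dS = f$dS, dG = f$dG),
                numeric(4))
  list(mean = rowMeans(mat),
       sd = if (length(fits) >= 3) apply(mat, 1, stats::sd) else
         stats::setNames(rep(NA_real_, 4), rownames(mat)),
       fits = fits, model = model, t_eval = t_eval)
}

#' Methylation difference energetics
#'
#' Differences between methylated and unmodified two-state fits:
#' \eqn{\Delta\Delta G = \Delta G_{m6A} - \Delta G_{unmod}} and likewise for
#' \eqn{\Delta\Delta H} and \eqn{\Delta\Delta S}. Values are signed: negative
#' \eqn{\Delta\Delta G} means methylation stabilises the fold. Uncertainties,
#' when both fits carry them, combine in quadrature.
#'
#' @param methylated,unmodified `melt_fit` objects (or lists with `dG`, `dH`,
#'   `dS`, `model`, `t_eval`, optional `se`), same model and `t_eval`.
#' @return list with `ddG`, `ddH`, `ddS`, `t_eval` and `se` (or NULL).
#' @export
delta_delta <- function(methylated, unmodified) {
  for (nm in c("dG", "dH", "dS", "model", "t_eval")) {
    if (is.null(methylated[[nm]]) || is.null(unmodified[[nm]]))
      stop_domain(sprintf("both fits must carry `%s`", nm), "m6aj_argument_error")
  }
  if (!identical(methylated$model, unmodified$model))
    stop_domain("fits have different models", "m6aj_argument_error")
  if (abs(methylated$t_eval - unmodified$t_eval) > 1e-9)
    stop_domain("fits were evaluated at different temperatures", "m6aj_argument_error")
  se <- NULL
  if (!is.null(methylated$se) && !is.null(unmodified$se)) {
    se <- sqrt(methylated$se[c("dG", "dH", "dS")]^2 +
               unmodified$se[c("dG", "dH", "dS")]^2)
    names(se) <- c("ddG", "ddH", "ddS")
  }
  list(ddG = methylated$dG - unmodified$dG,
       ddH = methylated$dH - unmodified$dH,
       ddS = methylated$dS - unmodified$dS,
       t_eval = methylated$t_eval, se = se)
}
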