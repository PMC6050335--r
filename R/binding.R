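#' Fluorescence polarization binding isotherms
#'
#' Anisotropy read-outs for protein titrated into a fixed, trace amount of
#' labelled RNA. `anisotropy_one_site()` uses the exact bound fraction from
#' the quadratic equilibrium solution,
#' \deqn{f_b = \frac{R_t + L_t + K_D - \sqrt{(R_t + L_t + K_D)^2 - 4 R_t L_t}}{2 R_t},}
#' and returns \eqn{A_t = A + (B - A) f_b}, so that \eqn{A_t = A} with no
#' protein and \eqn{A_t \to B} at saturation. `anisotropy_two_site()` models
#' two independent sites under the free-ligand approximation
#' (\eqn{L_{free} \approx L_t}, valid for trace RNA):
#' \deqn{A_t = \frac{A + B L/K_{D1} + C L^2/(K_{D1} K_{D2})}{1 + L/K_{D1} + L^2/(K_{D1} K_{D2})}.}
#'
#' @param Lt total protein concentration(s), mol/L, non-negative.
#' @param Rt total RNA concentration, mol/L (> 0).
#' @param KD,KD1,KD2 dissociation constants, mol/L (> 0).
#' @param A,B,C anisotropy endpoints: free RNA, RNA-protein, RNA-(protein)2.
#' @return Anisotropy value(s), vectorised over `Lt`.
#' @examples
#' anisotropy_one_site(0, Rt = 2e-9, KD = 1.8e-7, A = 0.05, B = 0.20)  # = A
#' anisotropy_two_site(1e-6, KD1 = 3e-7, KD2 = 5e-5, A = 0.05, B = 0.15, C = 0.25)
#' @name binding-models
NULL

#' @rdname binding-models
#' @export
anisotropy_one_site <- function(Lt, Rt, KD, A, B) {
  if (!is.finite(KD) || KD <= 0) stop_domain("`KD` must be > 0")
  if (!is.finite(Rt) || Rt <= 0) stop_domain("`Rt` must be > 0")
  if (any(Lt < 0)) stop_domain("protein concentrations must be non-negative")
  A + (B - A) * bound_fraction_one_site(Lt, Rt, KD)
}

bound_fraction_one_site <- function(Lt, Rt, KD) {
  s <- Rt + Lt + KD
  disc <- s^2 - 4 * Rt * Lt   # = (Rt - Lt + KD)^2 + 4*KD*Lt >= 0 always
  fb <- (s - sqrt(pmax(disc, 0))) / (2 * Rt)
  pmin(pmax(fb, 0), 1)
}

#' @rdname binding-models
#' @export
anisotropy_two_site <- function(Lt, KD1, KD2, A, B, C) {
  if (!is.finite(KD1) || KD1 <= 0 || !is.finite(KD2) || KD2 <= 0)
    stop_domain("dissociation constants must be > 0")
  if (any(Lt < 0)) stop_domain("protein concentrations must be non-negative")
  u <- Lt / KD1
  v <- Lt^2 / (KD1 * KD2)
  (A + B * u + C * v) / (1 + u + v)
}

#' Construct a titration curve object
#'
#' @param protein_conc total protein concentrations, mol/L (>= 6 points,
#'   including a zero or near-zero point); re-sorted ascending.
#' @param anisotropy observed anisotropy, same length.
#' @param rt total RNA concentration, mol/L.
#' @param intensity optional total fluorescence intensities per point.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(protein_conc, anisotropy, rt, intensity = NULL) {
  if (length(protein_conc) != length(anisotropy))
    stop_domain("protein_conc and anisotropy must have equal length")
  if (length(protein_conc) < 6L)
    stop_domain("a titration needs at least 6 points")
  if (any(protein_conc < 0)) stop_domain("protein concentrations must be >= 0")
  if (!is.finite(rt) || rt <= 0) stop_domain("`rt` must be > 0")
  if (!is.null(intensity) && length(intensity) != length(protein_conc))
    stop_domain("intensity must match the titration length")
  o <- order(protein_conc)
  structure(list(protein_conc = as.numeric(protein_conc)[o],
                 anisotropy = as.numeric(anisotropy)[o],
                 rt = rt,
                 intensity = if (is.null(intensity)) NULL else as.numeric(intensity)[o]),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %d points, Lt %.3g-%.3g M, Rt = %.3g M\n",
              length(x$protein_conc), min(x$protein_conc), max(x$protein_conc), x$rt))
  invisible(x)
}

# Small-sample corrected information criterion for a least-squares fit;
# k counts the fitted coefficients plus the noise variance.
aicc_ls <- function(rss, n, n_par) {
  k <- n_par + 1
  n * log(rss / n) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' Fit a binding isotherm to an anisotropy titration
#'
#' Least-squares fit of the one-site or two-independent-site model with a
#' deterministic multi-start strategy: dissociation constants are fitted on a
#' log10 scale and initialised on a log-spaced grid spanning the titrated
#' range; anisotropy endpoints start at the first/last observed values. The
#' start with the lowest residual sum of squares wins.
#'
#' When a fitted dissociation constant exceeds the largest titrated
#' concentration the estimate is flagged (`kd_lower_bound`) and should be
#' quoted as a lower bound, not a point estimate. Near-constant data are
#' returned with `kd_identifiable = FALSE`.
#'
#' @param curve a [titration_curve()].
#' @param model `"one_site"` or `"two_site"`.
#' @return An object of class `binding_fit` with the fitted constants (mol/L),
#'   endpoints, `rss`, small-sample-corrected information criterion `aicc`,
#'   and identifiability flags. Two-site fits also carry `rt_approx_ok`,
#'   FALSE when the trace-RNA free-ligand approximation is doubtful
#'   (Rt > 0.01 * KD1).
#' @export
fit_binding <- function(curve, model = c("one_site", "two_site")) {
  stopifnot(inherits(curve, "titration_curve"))
  model <- match.arg(model)
  L <- curve$protein_conc
  y <- curve$anisotropy
  n <- length(L)
  if (model == "two_site" && n < 8L)
    stop_domain("two-site fits need at least 8 points", "m6aj_argument_error")

  # degenerate flat data: endpoints equal, K unidentifiable
  if (stats::sd(y) < 1e-12) {
    return(structure(list(model = model, KD = if (model == "one_site") NA_real_,
                          KD1 = if (model == "two_site") NA_real_,
                          KD2 = if (model == "two_site") NA_real_,
                          A = mean(y), B = mean(y),
                          C = if (model == "two_site") mean(y),
                          rss = 0, aicc = -Inf, rt = curve$rt,
                          kd_identifiable = FALSE, kd_lower_bound = FALSE),
                     class = "binding_fit"))
  }

  pos <- L[L > 0]
  kgrid <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = 5)
  A0 <- y[1L]
  Bend <- y[n]
  Rt <- curve$rt

  best <- NULL
  best_rss <- Inf
  if (model == "one_site") {
    for (k0 in kgrid) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ anisotropy_one_site(L, Rt, 10^lk, A, B),
                          start = list(lk = log10(k0), A = A0, B = Bend),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (rss < best_rss - 1e-15) { best <- fit; best_rss <- rss }
      }
    }
    n_par <- 3
  } else {
    mid <- y[which.min(abs(L - stats::median(pos)))]
    for (k1 in kgrid) for (k2 in kgrid[kgrid >= k1]) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ anisotropy_two_site(L, 10^lk1, 10^lk2, A, B, C),
                          start = list(lk1 = log10(k1), lk2 = log10(k2),
                                       A = A0, B = mid, C = Bend),
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (rss < best_rss - 1e-15) { best <- fit; best_rss <- rss }
      }
    }
    n_par <- 5
  }
  if (is.null(best))
    stop(structure(class = c("m6aj_fit_error", "error", "condition"),
                   list(message = "binding fit failed to converge from all starts",
                        call = sys.call())))

  cf <- stats::coef(best)
  out <- list(model = model, rt = Rt, rss = best_rss,
              aicc = aicc_ls(best_rss, n, n_par), kd_identifiable = TRUE)
  if (model == "one_site") {
    out$KD <- 10^cf[["lk"]]
    out$A <- cf[["A"]]; out$B <- cf[["B"]]
    out$kd_lower_bound <- out$KD > max(L)
  } else {
    out$KD1 <- 10^cf[["lk1"]]; out$KD2 <- 10^cf[["lk2"]]
    out$A <- cf[["A"]]; out$B <- cf[["B"]]; out$C <- cf[["C"]]
    out$kd_lower_bound <- out$KD2 > max(L)
    out$rt_approx_ok <- Rt <= 0.01 * min(out$KD1, out$KD2)
  }
  structure(out, class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$model == "one_site") {
    cat(sprintf("<binding_fit:one_site> KD = %.3g M%s, A = %.3f, B = %.3f (rss %.3g, AICc %.1f)\n",
                x$KD, if (isTRUE(x$kd_lower_bound)) " (lower bound)" else "",
                x$A, x$B, x$rss, x$aicc))
  } else {
    cat(sprintf("<binding_fit:two_site> KD1 = %.3g M, KD2 = %.3g M%s, A/B/C = %.3f/%.3f/%.3f (rss %.3g, AICc %.1f)\n",
                x$KD1, x$KD2, if (isTRUE(x$kd_lower_bound)) " (KD2 lower bound)" else "",
                x$A, x$B, x$C, x$rss, x$aicc))
  }
  invisible(x)
}

#' Compare one-site and two-site fits of the same titration
#'
#' Fits both models and prefers the lower small-sample-corrected information
#' criterion (the criterion penalises the two extra two-site parameters).
#' With fewer than 8 points only the one-site model is fitted, with a warning.
#'
#' @param curve a [titration_curve()].
#' @return list with `preferred` ("one_site"/"two_site"), both fits and their
#'   criterion values.
#' @export
compare_binding_models <- function(curve) {
  one <- fit_binding(curve, "one_site")
  if (length(curve$protein_conc) < 8L) {
    warning("fewer than 8 points: restricted to the one-site model")
    return(list(preferred = "one_site", one_site = one, two_site = NULL,
                aicc = c(one_site = one$aicc, two_site = NA_real_)))
  }
  two <- tryCatch(fit_binding(curve, "two_site"), error = function(e) NULL)
  aicc <- c(one_site = one$aicc,
            two_site = if (is.null(two)) NA_real_ else two$aicc)
  preferred <- if (!is.na(aicc["two_site"]) && aicc["two_site"] < aicc["one_site"])
    "two_site" else "one_site"
  list(preferred = preferred, one_site = one, two_site = two, aicc = aicc)
}

#' Total-intensity quality control for FP titrations
#'
#' Anisotropy is only a clean binding read-out if total fluorescence intensity
#' stays roughly constant across the titration; a large spread signals
#' quenching or enhancement artefacts. The check computes
#' \eqn{(I_{max} - I_{min})/I_{min}} (about 5\% in well-behaved assays).
#'
#' @param intensities positive total intensities.
#' @param threshold maximum acceptable ratio (default 0.10).
#' @return list with `ratio` and logical `pass`.
#' @examples
#' check_intensity_qc(c(100, 105))  # ratio 0.05, pass
#' @export
check_intensity_qc <- function(intensities, threshold = 0.10) {
  if (length(intensities) < 2L || any(!is.finite(intensities)) || any(intensities <= 0))
    stop_domain("intensities must be positive and at least two",
                "m6aj_validation_error")
  ratio <- (max(intensities) - min(intensities)) / min(intensities)
  list(ratio = ratio, pass = ratio <= threshold)
}
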