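test_that("two-state melting models match independent arithmetic", {
  # frozen values computed by direct scalar evaluation of the closed forms
  expect_equal(fraction_folded_duplex(320, Tm = 330, dH = -40),
               0.7620129040597725, tolerance = 1e-12)
  expect_equal(fraction_folded_hairpin(335, Tm = 330, dH = -45),
               0.2642112815118821, tolerance = 1e-12)
})

test_that("melting curves pass through 0.5 at Tm and respect limits", {
  for (dH in c(-20, -45, -80, 10)) {
    expect_equal(fraction_folded_duplex(330, 330, dH), 0.5, tolerance = 1e-12)
    expect_equal(fraction_folded_hairpin(330, 330, dH), 0.5, tolerance = 1e-12)
  }
  # melted and folded limits, overflow-safe
  expect_equal(fraction_folded_hairpin(5000, 330, -45), 0, tolerance = 1e-6)
  expect_equal(fraction_folded_hairpin(30, 330, -45), 1, tolerance = 1e-6)
  expect_equal(fraction_folded_duplex(5000, 330, -40), 0, tolerance = 1e-3)
  expect_equal(fraction_folded_duplex(30, 330, -40), 1, tolerance = 1e-6)
  # monotone non-increasing in T for folding transitions (dH < 0)
  TT <- seq(280, 380, by = 0.5)
  for (dH in c(-25, -45, -70)) {
    expect_true(all(diff(fraction_folded_hairpin(TT, 330, dH)) <= 1e-12))
    expect_true(all(diff(fraction_folded_duplex(TT, 330, dH)) <= 1e-12))
  }
  expect_error(fraction_folded_hairpin(-5, 330, -45), class = "m6aj_domain_error")
  expect_error(fraction_folded_duplex(300, -1, -45), class = "m6aj_domain_error")
})

test_that("derive_thermo reproduces hand arithmetic and the Tm identities", {
  h <- derive_thermo(Tm = 330, dH = -45, model = "hairpin", t_eval = 310.15)
  expect_equal(h$dS, -0.136363636363636, tolerance = 1e-12)
  expect_equal(h$dG, -2.70681818181819, tolerance = 1e-9)
  d <- derive_thermo(Tm = 330, dH = -40, model = "duplex", ct = 3e-6,
                     t_eval = 310.15)
  expect_equal(d$dS, -40 / 330 - 0.0019872 * log(1.5e-6), tolerance = 1e-12)
  expect_equal(d$dG, -10.67107499097406, tolerance = 1e-9)
  # dG(Tm) = 0 for hairpin; = R*Tm*log(CT/2) for duplex
  expect_equal(derive_thermo(330, -45, "hairpin", t_eval = 330)$dG, 0,
               tolerance = 1e-12)
  expect_equal(derive_thermo(330, -40, "duplex", ct = 3e-6, t_eval = 330)$dG,
               0.0019872 * 330 * log(1.5e-6), tolerance = 1e-9)
  expect_error(derive_thermo(330, -40, "duplex"), class = "m6aj_argument_error")
})

test_that("delta_delta is a signed elementwise difference", {
  mk <- function(dG, dH = -45, dS = -0.1, model = "hairpin")
    list(dG = dG, dH = dH, dS = dS, model = model, t_eval = 310.15)
  expect_equal(delta_delta(mk(-3), mk(-3))$ddG, 0)
  # B5' contrast: methylated more stable
  expect_equal(delta_delta(mk(-3.0), mk(-2.1))$ddG, -0.9)
  # duplex contrast: methylated less stable
  expect_equal(delta_delta(mk(-4.0), mk(-4.6))$ddG, 0.6, tolerance = 1e-12)
  # swapping arguments negates all three quantities (thermodynamically
  # consistent inputs: dG = dH - T*dS)
  mk2 <- function(dH, dS) list(dG = dH - 310.15 * dS, dH = dH, dS = dS,
                               model = "hairpin", t_eval = 310.15)
  a <- mk2(-46, -0.14); b <- mk2(-42, -0.12)
  ab <- delta_delta(a, b); ba <- delta_delta(b, a)
  expect_equal(ab$ddG, -ba$ddG)
  expect_equal(ab$ddH, -ba$ddH)
  expect_equal(ab$ddS, -ba$ddS)
  expect_equal(ab$ddG, ab$ddH - 310.15 * ab$ddS, tolerance = 1e-9)
  expect_error(delta_delta(mk(-3), mk(-3, model = "duplex")),
               class = "m6aj_argument_error")
})

test_that("fit_melting recovers exact parameters from noise-free curves", {
  ch <- gen_melting_curve("hairpin", Tm = 330, dH = -45, sigma = 0)
  fh <- fit_melting(ch, "hairpin")
  expect_equal(fh$Tm, 330, tolerance = 1e-7)
  expect_equal(fh$dH, -45, tolerance = 1e-7)
  expect_equal(fh$dG, fh$dH - 310.15 * fh$dS, tolerance = 1e-9)
  cd <- gen_melting_curve("duplex", Tm = 330, dH = -60, ct = 3e-6, sigma = 0)
  fd <- fit_melting(cd, "duplex")
  expect_equal(fd$Tm, 330, tolerance = 1e-7)
  expect_equal(fd$dH, -60, tolerance = 1e-7)
})

test_that("fit_melting handles raw absorbance with joint linear baselines", {
  TT <- seq(15, 95, length.out = 81) + 273.15
  f <- fraction_folded_hairpin(TT, 330, -45)
  abs_sig <- (0.80 - 2e-4 * TT) * f + (1.05 + 1e-4 * TT) * (1 - f)
  cv <- melting_curve(TT, abs_sig, signal_kind = "absorbance")
  fit <- fit_melting(cv, "hairpin", baseline = "linear")
  expect_equal(fit$Tm, 330, tolerance = 1e-4)
  expect_equal(fit$dH, -45, tolerance = 1e-3)
  expect_error(fit_melting(cv, "hairpin", baseline = "none"),
               class = "m6aj_argument_error")
})

test_that("fit_melting validates inputs", {
  cv <- melting_curve(seq(290, 360, length.out = 20),
                      seq(1.4, 0, length.out = 20), signal_kind = "fraction")
  expect_error(fit_melting(cv, "hairpin"), class = "m6aj_validation_error")
  cd <- gen_melting_curve("hairpin", 330, -45, sigma = 0)  # no ct attached
  expect_error(fit_melting(cd, "duplex"), class = "m6aj_argument_error")
  expect_error(melting_curve(c(300, 299, 310, 311, 312, 313, 314, 315),
                             rep(0.5, 8)), class = "m6aj_domain_error")
  expect_error(melting_curve(300:306, rep(0.5, 7)), class = "m6aj_domain_error")
})

test_that("noisy melting fits recover Tm and dH within tolerance", {
  hits <- vapply(1:40, function(k) {
    cc <- gen_melting_curve("hairpin", Tm = 330, dH = -45, sigma = 0.01,
                            seed = 6000 + k)
    f <- fit_melting(cc, "hairpin")
    c(abs(f$Tm - 330) < 0.5, abs(f$dH + 45) / 45 < 0.05)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})

test_that("replicate fits report scatter and bootstrap gives uncertainties", {
  curves <- lapply(1:3, function(k)
    gen_melting_curve("hairpin", 330, -45, sigma = 0.01, seed = 50 + k))
  rep_fit <- fit_melting_replicates(curves, "hairpin")
  expect_equal(unname(rep_fit$mean["Tm"]), 330, tolerance = 1e-3)
  expect_true(all(is.finite(rep_fit$sd)))
  f <- fit_melting(curves[[1]], "hairpin", n_boot = 25, boot_seed = 9L)
  expect_true(all(f$se > 0))
  expect_named(f$se, c("Tm", "dH", "dS", "dG"))
})
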