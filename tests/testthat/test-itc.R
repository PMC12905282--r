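test_that("free ligand solves the mass balance exactly", {
  m <- one_set_model(n = 1, K = 1e6, dH = -10)

  # no macromolecule or no binding: all ligand stays free
  expect_equal(free_ligand(m, 0, 1e-5), 1e-5)
  expect_equal(free_ligand(one_set_model(1, 0, -10), 1e-5, 1e-5), 1e-5)

  # closed-form quadratic root oracle for one set of sites:
  # K X^2 + (1 + K (Mt - Xt)) X - Xt = 0
  Mt <- 15e-6; Xt <- 10e-6; K <- 1e6
  bq <- 1 + K * (Mt - Xt)
  X_quad <- (-bq + sqrt(bq^2 + 4 * K * Xt)) / (2 * K)
  expect_equal(free_ligand(m, Mt, Xt), X_quad, tolerance = 1e-10)

  # bisection oracle on random draws; residual below 1e-12 * Xt
  set.seed(11)
  for (i in 1:200) {
    mm <- two_sets_model(runif(1, .1, 2), runif(1, .1, 2),
                         10^runif(1, 3, 9), 10^runif(1, 3, 9),
                         -8, -12)
    Mt <- runif(1, 0, 1e-4); Xt <- runif(1, 1e-9, 2e-4)
    X <- free_ligand(mm, Mt, Xt)
    resid <- abs(Xt - X - Mt * sum(mm$n * mm$K * X / (1 + mm$K * X)))
    expect_lt(resid, 1e-12 * max(Xt, 1e-12))
    bal <- function(x) x + Mt * sum(mm$n * mm$K * x / (1 + mm$K * x)) - Xt
    lo <- 0; hi <- Xt
    for (k in 1:80) {                      # plain bisection oracle
      mid <- (lo + hi) / 2
      if (bal(mid) > 0) hi <- mid else lo <- mid
    }
    expect_lt(abs(X - (lo + hi) / 2), 1e-10 * max(Xt, 1e-12))
  }

  expect_error(free_ligand(m, NA, 1e-5), "finite")
})

test_that("cumulative heat matches the binding equations and their limits", {
  prot <- default_protocol()
  m1 <- one_set_model(1, 1e7, -10)

  expect_equal(cumulative_heat(m1, prot, 15e-6, 0), 0)

  # saturation limit: Q -> Mt V0 n dH
  Qsat <- cumulative_heat(m1, prot, 15e-6, 1)      # vast ligand excess
  expect_equal(Qsat, 15e-6 * prot$V0 * 1 * -10, tolerance = 1e-3)

  # two sets with n2 = 0 equals one set at identical (n1, K1, dH1)
  m2 <- structure(list(kind = "two_sets", n = c(1, 0), K = c(1e7, 1e5),
                       dH = c(-10, -5)), class = "binding_model")
  for (Xt in c(1e-6, 5e-6, 2e-5))
    expect_equal(cumulative_heat(m2, prot, 15e-6, Xt),
                 cumulative_heat(m1, prot, 15e-6, Xt), tolerance = 1e-12)

  # two sets with equal (K, dH) equals one set with n = n1 + n2, on a grid
  ma <- two_sets_model(0.3, 0.7, 2e6, 2e6, -9, -9)
  mb <- one_set_model(1.0, 2e6, -9)
  for (Xt in seq(1e-7, 3e-5, length.out = 15))
    expect_equal(cumulative_heat(ma, prot, 15e-6, Xt),
                 cumulative_heat(mb, prot, 15e-6, Xt), tolerance = 1e-10)
})

test_that("displaced-volume correction reduces to known identities", {
  Q <- c(-1, -1.8, -2.3, -2.5) * 1e-8
  V0 <- 2e-4
  # dVi = 0: plain first difference
  expect_equal(displaced_volume_correction(Q, rep(0, 4), V0),
               diff(c(0, Q)), tolerance = 1e-12)
  # constant Q across injections: qi = (dVi/V0) Q (first injection still
  # sees Q0 = 0, so the identity applies from the second on)
  dV <- rep(1e-6, 4)
  qc <- displaced_volume_correction(rep(-2e-8, 4), dV, V0)
  expect_equal(qc[2:4], rep((1e-6 / V0) * -2e-8, 3), tolerance = 1e-12)
  expect_equal(qc[1], -2e-8 + (1e-6 / V0) * -1e-8, tolerance = 1e-12)
})

test_that("injection heats carry the dilution bookkeeping", {
  prot <- default_protocol()
  iso <- injection_heats(cooperative_truth(), prot)
  expect_s3_class(iso, "isotherm")
  expect_equal(nrow(iso), 37L)
  expect_false(is.unsorted(iso$molar_ratio))

  # perfusion concentrations
  v <- cumsum(prot$dV)
  expect_equal(iso$Mt, prot$Mt0 * exp(-v / prot$V0))
  expect_equal(iso$Xt, prot$Xs * (1 - exp(-v / prot$V0)))

  # sum of injection heats equals final cumulative heat up to the
  # correction terms (term-by-term ledger oracle)
  corr <- (iso$dV / prot$V0) * (iso$Q + c(0, iso$Q[-37])) / 2
  expect_equal(sum(iso$q), iso$Q[37] + sum(corr), tolerance = 1e-12)

  # late injections approach zero heat at saturation
  expect_lt(abs(iso$q[37]), abs(iso$q[1]) / 20)
})

test_that("noiseless fits recover generating parameters to 0.1%", {
  prot <- default_protocol()

  m1 <- one_set_model(1, 1e7, -10)
  f1 <- fit_isotherm(injection_heats(m1, prot), prot, "one_set")
  expect_true(f1$converged)
  expect_equal(f1$estimates$n, 1, tolerance = 1e-3)
  expect_equal(f1$estimates$K, 1e7, tolerance = 1e-3)
  expect_equal(f1$estimates$dH, -10, tolerance = 1e-3)

  f2 <- fit_isotherm(injection_heats(cooperative_truth(), prot),
                     prot, "two_sets")
  expect_true(f2$converged)
  expect_equal(cooperativity_index(f2), 100, tolerance = 1e-2)
  expect_equal(sum(f2$estimates$n), 0.5, tolerance = 1e-3)

  # degenerate inputs
  iso0 <- injection_heats(m1, prot)
  iso0$q <- rep(0, nrow(iso0))
  expect_error(fit_isotherm(iso0, prot, "one_set"), "no binding signal")
})

test_that("cooperativity index follows the weak/tight ordering convention", {
  prot <- default_protocol()
  # swap which set is labelled "1" in the generator: index must not change
  fa <- fit_isotherm(injection_heats(
    two_sets_model(0.25, 0.25, 1e6, 1e8, -8, -12), prot), prot, "two_sets")
  fb <- fit_isotherm(injection_heats(
    two_sets_model(0.25, 0.25, 1e8, 1e6, -12, -8), prot), prot, "two_sets")
  expect_equal(cooperativity_index(fa), cooperativity_index(fb),
               tolerance = 1e-6)
  expect_gte(cooperativity_index(fa), 1)

  # identical sets give an index of 1
  feq <- fit_isotherm(injection_heats(
    two_sets_model(0.25, 0.25, 1e7, 1e7, -10, -10), prot), prot, "two_sets")
  expect_equal(cooperativity_index(feq), 1, tolerance = 0.05)

  expect_error(cooperativity_index(
    fit_isotherm(injection_heats(one_set_model(1, 1e7, -10), prot),
                 prot, "one_set")), "two-sets")
})

test_that("thermodynamics identities hold", {
  expect_equal(thermodynamics(one_set_model(1, 1, -5))$dG, 0)
  td <- thermodynamics(one_set_model(1, 1e6, -10), temperature = 298.15)
  expect_equal(td$dG, -1.987204e-3 * 298.15 * log(1e6), tolerance = 1e-12)
  expect_equal(td$dG, -8.19, tolerance = 1e-3)
  expect_equal(td$TdS + td$dG, td$dH, tolerance = 1e-14)
  expect_equal(td$KD * 1e6, 1)
  expect_error(thermodynamics(structure(list(kind = "one_set", n = 1, K = 0,
                                             dH = -1),
                                        class = "binding_model")),
               "positive")
})

test_that("itc_fit methods behave like a fitted model object", {
  prot <- default_protocol()
  truth <- one_set_model(1, 1e7, -10)
  iso <- gen_itc(truth, prot, noise_sd = 2e-10, seed = 4)
  fit <- fit_isotherm(iso, prot, "one_set")
  expect_length(coef(fit), 3L)
  expect_length(predict(fit), 37L)
  expect_equal(residuals(fit), iso$q - predict(fit))
  expect_output(print(fit), "one_set")
  expect_output(summary(fit), "Thermodynamics")
  sim <- simulate(fit, seed = 1)
  expect_s3_class(sim, "isotherm")
  # c-value warnings outside [1, 1000]
  weak <- fit_isotherm(injection_heats(one_set_model(1, 2e4, -10), prot),
                       prot, "one_set")
  expect_true(length(weak$warnings) > 0)
})
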