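test_that("buffer subtraction propagates uncertainty in quadrature", {
  q <- seq(0.01, 0.3, length.out = 50)
  s <- scattering_curve(q, 100 * exp(-q^2 * 100), sigma = rep(2, 50))
  b <- scattering_curve(q, rep(5, 50), sigma = rep(1.5, 50))

  zero <- scattering_curve(q, rep(0, 50), sigma = rep(0, 50))
  expect_equal(buffer_subtract(s, zero)$I, s$I)

  same <- buffer_subtract(s, s)
  expect_true(all(same$I == 0))
  expect_equal(same$sigma, sqrt(2) * s$sigma)

  out <- buffer_subtract(s, b)
  expect_equal(out$sigma^2, s$sigma^2 + b$sigma^2)

  b_shift <- scattering_curve(q + 1e-4, b$I, b$sigma)
  expect_error(buffer_subtract(s, b_shift), "grids differ")
  expect_silent(buffer_subtract(s, b_shift, interpolate = TRUE))
})

test_that("Guinier fit recovers Rg on ideal and analytic curves", {
  # exact on a pure Guinier-law curve
  g <- guinier_fit(gaussian_curve(Rg = 20))
  expect_equal(g$Rg, 20, tolerance = 1e-6)
  expect_equal(g$I0, 5e3, tolerance = 1e-6)
  expect_lte(g$qmax_rg, 1.3)

  # solid sphere: Rg = sqrt(3/5) R within 1%
  g_sph <- guinier_fit(sphere_curve(R = 30))
  expect_equal(g_sph$Rg, sqrt(3 / 5) * 30, tolerance = 0.01)

  # truncation before 5 usable points
  cur <- gaussian_curve(Rg = 20, n = 3, qmax = 0.02)
  expect_error(guinier_fit(cur), "too few|fewer than")

  # rising low-q intensity has no Guinier slope
  q <- seq(0.005, 0.1, length.out = 60)
  rising <- scattering_curve(q, 10 + 500 * q^2, sigma = rep(0.1, 60))
  expect_error(guinier_fit(rising), "failed")
})

test_that("Guinier Rg agrees with exact bead-model Rg within 2%", {
  for (N in c(4L, 8L, 16L, 24L)) {
    for (mk in list(open_chain, looped_chain)) {
      m <- mk(N)
      q <- exp(seq(log(0.15 / bead_rg(m)), log(0.3), length.out = 300))
      g <- guinier_fit(gen_saxs(m, q, snr = Inf))
      expect_equal(g$Rg, bead_rg(m), tolerance = 0.02)
    }
  }
})

test_that("dimensionless Kratky peaks at (sqrt(3), 3/e) for a globule", {
  cur <- gaussian_curve(Rg = 25, n = 3000, qmax = 0.4)
  g <- guinier_fit(cur)
  k <- dimensionless_kratky(cur, g)
  expect_lt(k$kratky[1], 1e-3)   # first grid point sits near, not at, q = 0
  i <- which.max(k$kratky)
  expect_equal(k$qRg[i], sqrt(3), tolerance = 0.005)
  expect_equal(k$kratky[i], 3 / exp(1), tolerance = 0.005)
  expect_equal(unname(attr(k, "reference")), c(sqrt(3), 3 / exp(1)))

  # extended chain plateaus above the globular maximum at high qRg
  m <- open_chain(16)
  q <- seq(0.004, 0.35, length.out = 500)
  cur_c <- gen_saxs(m, q, snr = Inf)
  kc <- dimensionless_kratky(cur_c, guinier_fit(cur_c))
  high <- kc$kratky[kc$qRg > 3 & kc$qRg < 8]
  expect_gt(stats::median(high), 3 / exp(1))
})

test_that("correlation volume matches the Gaussian closed form", {
  cur <- gaussian_curve(Rg = 20)
  g <- guinier_fit(cur)
  vc <- correlation_volume_mw(cur, g)
  expect_equal(vc$Vc, 2 * 20^2 / 3, tolerance = 0.01)

  # invariant under intensity rescaling
  cur5 <- scattering_curve(cur$q, 5 * cur$I, 5 * cur$sigma)
  vc5 <- correlation_volume_mw(cur5, guinier_fit(cur5))
  expect_equal(vc5$Vc, vc$Vc, tolerance = 1e-6)

  expect_error(correlation_volume_mw(gaussian_curve(Rg = 20, qmax = 0.05),
                                     g, integration_qmax = 0.3),
               "does not extend")
})

test_that("optimal scale and chi-square follow the analytic formulas", {
  cur <- sphere_curve()
  expect_equal(optimal_scale(cur, cur), 1, tolerance = 1e-12)

  fifth <- scattering_curve(cur$q, cur$I / 5, cur$sigma)
  expect_equal(optimal_scale(cur, fifth), 5, tolerance = 1e-12)

  # the analytic c attains the chi2 minimum over a dense grid
  set.seed(8)
  theor <- scattering_curve(cur$q, cur$I * 0.7 + mean(cur$I) * 0.01,
                            cur$sigma)
  c_opt <- optimal_scale(cur, theor)
  chi_opt <- chi_square(cur, theor)$chi2
  for (cc in seq(0.5 * c_opt, 2 * c_opt, length.out = 400))
    expect_gte(chi_square(cur, theor, c_scale = cc)$chi2 + 1e-10, chi_opt)

  # exact and scaled self-comparison give chi2 = 0
  expect_lt(chi_square(cur, cur)$chi2, 1e-20)
  tripled <- scattering_curve(cur$q, 3 * cur$I, cur$sigma)
  expect_lt(chi_square(cur, tripled)$chi2, 1e-18)

  # one-sigma offset at forced c = 1: chi2 = N/(N-1)
  n <- length(cur$q)
  shifted <- scattering_curve(cur$q, cur$I + cur$sigma, cur$sigma)
  expect_equal(chi_square(shifted, cur, c_scale = 1)$chi2, n / (n - 1),
               tolerance = 1e-12)

  expect_error(optimal_scale(cur, scattering_curve(cur$q, rep(0, n),
                                                   cur$sigma)),
               "degenerate")
  expect_error(chi_square(cur, scattering_curve(cur$q[-1], cur$I[-1],
                                                cur$sigma[-1])),
               "common q grid")
})

test_that("chi-square is invariant under rescaling of the model curve", {
  cur <- sphere_curve()
  set.seed(2)
  theor <- scattering_curve(cur$q, cur$I * (1 + rnorm(length(cur$q), 0, .02)),
                            cur$sigma)
  base <- chi_square(cur, theor)$chi2
  for (a in c(0.1, 3, 1000))
    expect_equal(chi_square(cur, scattering_curve(cur$q, a * theor$I,
                                                  theor$sigma))$chi2,
                 base, tolerance = 1e-9)
  expect_gt(base, 0)
})

test_that("pair distribution recovers sphere geometry", {
  cur <- sphere_curve(R = 30)
  pr <- pair_distribution(cur)

  # Dmax within 10% of 2R
  expect_equal(pr$dmax, 60, tolerance = 0.10)

  # endpoints exactly zero, nonnegative everywhere with positivity on
  expect_identical(pr$p[1], 0)
  expect_identical(pr$p[length(pr$p)], 0)
  expect_true(all(pr$p >= 0))

  # Rg from the second moment matches the Guinier Rg within 3%
  g <- guinier_fit(cur)
  expect_equal(pr$rg, g$Rg, tolerance = 0.03)

  # back-transform quality on noiseless synthetic data
  expect_lte(pr$back_chi2, 1.5)

  # p(r) shape matches the Monte-Carlo pairwise-distance oracle of
  # uniform points in a sphere
  set.seed(9)
  pts <- matrix(runif(3 * 4000, -1, 1), ncol = 3)
  pts <- 30 * pts[rowSums(pts^2) <= 1, ][1:1200, ]
  d <- as.numeric(dist(pts))
  h <- hist(d, breaks = seq(0, 60, length.out = 30), plot = FALSE)
  keep <- h$mids <= max(pr$r)
  p_interp <- approx(pr$r, pr$p, xout = h$mids[keep])$y
  expect_gt(cor(h$density[keep], p_interp), 0.98)
})

test_that("looped chains report smaller Dmax than open chains (full path)", {
  for (N in c(8L, 16L)) {
    po <- pair_distribution(gen_saxs(open_chain(N),
                                     seq(0.004, 0.25, length.out = 300),
                                     snr = 60, seed = N))
    pl <- pair_distribution(gen_saxs(looped_chain(N),
                                     seq(0.004, 0.25, length.out = 300),
                                     snr = 60, seed = N + 50L))
    expect_lt(pl$dmax, po$dmax)
    # mirrors the exact-coordinate oracle
    expect_lt(bead_dmax(looped_chain(N)), bead_dmax(open_chain(N)))
  }
})

test_that("stable-frame selection finds the elution plateau", {
  q <- seq(0.008, 0.25, length.out = 120)
  mkframe <- function(Rg, seed) {
    set.seed(seed)
    I <- 1e4 * exp(-q^2 * Rg^2 / 3)
    sig <- 0.02 * I + 1
    scattering_curve(q, I + rnorm(120, 0, sig), sig)
  }
  # drifting edges, stable plateau in frames 5..12
  rgs <- c(40, 36, 33, 30, rep(25, 8), 21, 19)
  ser <- sec_saxs_series(lapply(seq_along(rgs),
                                function(i) mkframe(rgs[i], i)))
  sel <- select_stable_frames(ser, rg_tolerance = 0.05)
  expect_equal(which(sel$mask), 5:12)

  # averaged curve has pointwise sigma below any single frame
  expect_true(all(sel$curve$sigma <=
                    apply(sapply(ser$frames[sel$mask], `[[`, "sigma"),
                          1, min) + 1e-12))

  # identical frames: everything selected, average equals any frame
  same <- sec_saxs_series(replicate(5, mkframe(25, 99), simplify = FALSE))
  sel2 <- select_stable_frames(same)
  expect_true(all(sel2$mask))
  expect_equal(sel2$curve$I, same$frames[[1]]$I)

  # single frame comes back as-is
  one <- sec_saxs_series(list(mkframe(25, 1)))
  expect_equal(select_stable_frames(one)$curve$I, one$frames[[1]]$I)
})
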