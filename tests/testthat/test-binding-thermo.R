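test_that("free ligand solves the mass balance in limits and closed form", {
  one <- binding_parameters("one_site", kd1 = 1e-6, dh1 = -5e4)
  expect_equal(free_ligand(1e-6, 0, one), 1e-6)
  weak <- binding_parameters("one_site", kd1 = 1e3, dh1 = -5e4)
  expect_equal(free_ligand(1e-6, 1e-5, weak), 1e-6, tolerance = 1e-6)
  # equimolar at kd: golden-ratio root of the quadratic
  expect_equal(free_ligand(1e-6, 1e-6, one) / 1e-6, (sqrt(5) - 1) / 2,
               tolerance = 1e-12)
})

test_that("two-site free ligand agrees with an independent bisection oracle", {
  set.seed(101)
  for (i in 1:40) {
    kd1 <- 10^runif(1, -9, -4)
    kd2 <- kd1 * 10^runif(1, 0, 3)
    p <- 10^runif(1, -6, -4)
    l <- 10^runif(1, -7, -3.5)
    par <- binding_parameters("two_site", kd1 = kd1, kd2 = kd2,
                              dh1 = -5e4, dh2 = -4e4)
    got <- free_ligand(l, p, par)
    ora <- oracle_free_ligand_two_site(l, p, kd1, kd2)
    expect_equal(got, ora, tolerance = 1e-8)
    # mass-balance residual below 1e-12 relative
    z <- 1 + got / kd1 + got^2 / (kd1 * kd2)
    bound <- p / z * (got / kd1 + 2 * got^2 / (kd1 * kd2))
    expect_lt(abs(got + bound - l) / l, 1e-12)
  }
})

test_that("isotherm limits: zero enthalpy gives pure dilution heat, saturation approaches it", {
  des <- itc_design()
  exp0 <- itc_experiment(des$cell_volume, des$cell_conc, des$syringe_conc,
                         rep(des$injection_volume, des$n_injections))
  flat <- binding_parameters("one_site", kd1 = 1e-7, dh1 = 0, q_dil = 3e-7)
  expect_equal(itc_isotherm(flat, exp0), rep(3e-7, 35))
  sat <- binding_parameters("one_site", kd1 = 1e-9, dh1 = -5e4, q_dil = 1e-7)
  h <- itc_isotherm(sat, exp0)
  expect_lt(abs(h[35] - 1e-7), abs(h[1] - 1e-7) * 0.01)
})

test_that("first-injection heat matches a fine-grained incremental mixing oracle", {
  # one-site, kd 100 nM, dH -50 kJ/mol, 8 ul of 200 uM into 1.4 ml of 10 uM
  kd <- 1e-7; dh <- -5e4; v0 <- 1.4e-3; vinj <- 8e-6
  p0 <- 1e-5; csyr <- 2e-4
  par <- binding_parameters("one_site", kd1 = kd, dh1 = dh)
  exp1 <- itc_experiment(v0, p0, csyr, rep(vinj, 30))
  got <- itc_isotherm(par, exp1)[1]
  # oracle: the same overflow convention applied in 1e4 micro-injections,
  # complex concentration from the stable quadratic at every step
  n_steps <- 1e4
  dv <- vinj / n_steps
  p <- p0; l <- 0
  cplx <- function(p, l) {
    s <- p + l + kd
    2 * p * l / (s + sqrt(s^2 - 4 * p * l))
  }
  q <- 0
  for (k in seq_len(n_steps)) {
    d <- v0 / (v0 + dv)
    p_new <- p * d
    l_new <- l * d + csyr * dv / (v0 + dv)
    q <- q + v0 * dh * (cplx(p_new, l_new) - d * cplx(p, l))
    p <- p_new; l <- l_new
  }
  expect_equal(got, q, tolerance = 1e-3)
})

test_that("heat bookkeeping is conserved across the titration", {
  fx <- fixture_preset("sl2_itc")
  des <- fx$design
  exp0 <- itc_experiment(des$cell_volume, des$cell_conc, des$syringe_conc,
                         rep(des$injection_volume, des$n_injections))
  par <- fx$params
  h <- itc_isotherm(par, exp0)
  # recompute final cell enthalpy content and the expelled-complex ledger
  v0 <- des$cell_volume
  p <- par$n * des$cell_conc; l <- 0
  content <- function(p_tot, l_tot) {
    lf <- free_ligand(l_tot, p_tot, par)
    z <- 1 + lf / par$kd1 + lf^2 / (par$kd1 * par$kd2)
    pf <- p_tot / z
    v0 * (pf * lf / par$kd1 * par$dh1 +
            pf * lf^2 / (par$kd1 * par$kd2) * (par$dh1 + par$dh2))
  }
  expelled <- 0
  h_prev <- 0
  for (i in seq_len(des$n_injections)) {
    v <- des$injection_volume
    d <- v0 / (v0 + v)
    expelled <- expelled + (1 - d) * h_prev
    p <- p * d
    l <- l * d + des$syringe_conc * v / (v0 + v)
    h_prev <- content(p, l)
  }
  total <- h_prev + expelled + des$n_injections * par$q_dil
  expect_equal(sum(h), total, tolerance = 1e-9)
})

test_that("a very weak second site reduces the two-site isotherm to one-site", {
  des <- itc_design(n_injections = 5L)  # total ligand stays below one site
  exp0 <- itc_experiment(des$cell_volume, des$cell_conc, des$syringe_conc,
                         rep(des$injection_volume, des$n_injections))
  one <- binding_parameters("one_site", kd1 = 1e-7, dh1 = -6e4)
  two <- binding_parameters("two_site", kd1 = 1e-7, kd2 = 1e-3,
                            dh1 = -6e4, dh2 = -6e4)
  h1 <- itc_isotherm(one, exp0)
  h2 <- itc_isotherm(two, exp0)
  expect_true(all(abs(h2 - h1) <= 0.005 * abs(h1)))
})

test_that("noise-free parameter recovery is essentially exact for both models", {
  des <- itc_design()
  one <- binding_parameters("one_site", kd1 = 8e-7, dh1 = -6.5e4, q_dil = -4e-7)
  e1 <- make_itc(one, des, noise_frac = 0, seed = 1)
  f1 <- fit_itc(e1, "one_site", seed = 1)
  expect_true(f1$converged)
  expect_equal(f1$params$kd1, one$kd1, tolerance = 1e-3)
  expect_equal(f1$params$dh1, one$dh1, tolerance = 1e-3)
  expect_equal(f1$params$q_dil, one$q_dil, tolerance = 1e-2)

  fx <- fixture_preset("sl2_itc")
  e2 <- make_itc(fx$params, fx$design, noise_frac = 0, seed = 1)
  f2 <- fit_itc(e2, "two_site", seed = 1)
  expect_true(f2$converged)
  expect_equal(f2$params$kd1, fx$params$kd1, tolerance = 1e-3)
  expect_equal(f2$params$kd2, fx$params$kd2, tolerance = 1e-3)
  expect_equal(f2$params$dh1, fx$params$dh1, tolerance = 1e-3)
  expect_equal(f2$params$dh2, fx$params$dh2, tolerance = 1e-3)
  # free energy / entropy decomposition is consistent with the constants
  expect_equal(f2$dg1, 8.314 * 298 * log(f2$params$kd1), tolerance = 1e-9)
  expect_equal(f2$tds1, f2$params$dh1 - f2$dg1, tolerance = 1e-9)
})

test_that("a one-site fit to genuinely two-site data leaves more residual", {
  fx <- fixture_preset("sl2_itc")
  e <- make_itc(fx$params, fx$design, noise_frac = 0.01, seed = 7)
  f_two <- fit_itc(e, "two_site", seed = 7)
  f_one <- fit_itc(e, "one_site", seed = 7)
  expect_gt(f_one$rss, f_two$rss)
})

test_that("fitting requires enough injections", {
  des <- itc_design(n_injections = 8L)
  e <- make_itc(binding_parameters("one_site", kd1 = 1e-6, dh1 = -5e4), des,
                noise_frac = 0, seed = 1)
  expect_error(fit_itc(e, "one_site"), "at least 10")
})

test_that("slow-exchange estimator: equal integrals give Kd = C/2 and round trips are exact", {
  tot <- 5.4e-4
  eq <- data.frame(resonance_id = c("a", "b"), i_free = c(1, 2), i_bound = c(1, 2))
  est <- kd_from_integrals(eq, tot, tot)
  expect_equal(est$kd_mean, tot / 2, tolerance = 1e-12)
  expect_equal(est$kd_sd, 0)

  # inverse + estimator is identity over seven decades of Kd
  for (kd in 10^seq(-9, -2)) {
    f <- bound_fraction_forward(kd, tot, tot)
    expect_equal(f, oracle_bound_fraction(kd, tot, tot), tolerance = 1e-9)
    pr <- data.frame(resonance_id = "r", i_free = 1 - f, i_bound = f)
    expect_equal(kd_from_integrals(pr, tot, tot)$kd_mean / kd, 1,
                 tolerance = 1e-9)
  }
  # unequal totals use the general quadratic
  kd <- 3e-6; p <- 2e-4; r <- 7e-4
  f <- bound_fraction_forward(kd, p, r)
  pr <- data.frame(resonance_id = "r", i_free = 1 - f, i_bound = f)
  expect_equal(kd_from_integrals(pr, p, r)$kd_mean / kd, 1, tolerance = 1e-9)
})

test_that("slow-exchange estimator limits and error handling", {
  expect_lt(bound_fraction_forward(1, 1e-4, 1e-4), 1e-3)        # kd >> C
  expect_gt(bound_fraction_forward(1e-12, 1e-4, 1e-4), 0.999)   # kd << C
  bad <- data.frame(resonance_id = "r", i_free = 0, i_bound = 1)
  expect_error(kd_from_integrals(bad, 1e-4, 1e-4), "slow-exchange")
  expect_error(kd_from_integrals(data.frame(x = 1), 1e-4, 1e-4), "columns")
  noisy <- make_integral_pairs(1e-4, 5.4e-4, 5.4e-4, n_pairs = 4,
                               noise_cv = 0.05, seed = 2)
  est <- kd_from_integrals(noisy, 5.4e-4, 5.4e-4)
  expect_gt(est$kd_sd, 0)
  expect_lt(abs(log(est$kd_mean / 1e-4)), log(1.5))
})
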