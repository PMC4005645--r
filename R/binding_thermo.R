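# ---- Binding thermodynamics: ITC isotherms and slow-exchange NMR Kd --------

#' Binding model parameters
#'
#' Macroscopic parameters of a one-site (P + L <-> PL) or sequential two-site
#' (P + L <-> PL, PL + L <-> PL2) binding model of a ligand L binding a
#' protein P (for the RsmE homodimer, L is the RNA and the two events are the
#' first and second RNA molecule binding the dimer). Constants are
#' macroscopic, as reported by two-site calorimetry fits; no statistical
#' factor conversion to microscopic constants is applied.
#'
#' @param model `"one_site"` or `"two_site"`.
#' @param kd1 Dissociation constant of the first binding event (molar).
#' @param kd2 Dissociation constant of the second event (molar; two-site only).
#' @param dh1,dh2 Binding enthalpies per mole of event (J/mol).
#' @param n Stoichiometry / active-fraction correction multiplying the cell
#'   protein concentration (dimensionless, near 1).
#' @param q_dil Per-injection dilution-heat offset (J).
#' @return Object of class `binding_parameters`.
#' @export
binding_parameters <- function(model = c("one_site", "two_site"),
                               kd1, kd2 = NA_real_, dh1, dh2 = NA_real_,
                               n = 1, q_dil = 0) {
  model <- match.arg(model)
  stopifnot(kd1 > 0, is.finite(dh1))
  if (model == "two_site") {
    stopifnot(kd2 > 0, is.finite(dh2))
    if (kd2 < kd1) warning("kd2 < kd1: second event tighter than first ",
                           "(negative-cooperativity convention violated)")
  }
  structure(list(model = model, kd1 = kd1, kd2 = kd2, dh1 = dh1, dh2 = dh2,
                 n = n, q_dil = q_dil),
            class = "binding_parameters")
}

#' Titration experiment design (and optionally measured heats)
#'
#' @param cell_volume Calorimeter cell volume (litres).
#' @param cell_conc Protein concentration in the cell (molar; dimer
#'   concentration for the homodimer models).
#' @param syringe_conc Ligand (RNA) concentration in the syringe (molar).
#' @param injection_volumes Vector of injection volumes (litres).
#' @param temperature Kelvin.
#' @param heats Measured integrated injection heats (J), or `NULL` for a pure
#'   design used in simulation.
#' @return Object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_volume, cell_conc, syringe_conc,
                           injection_volumes, temperature = 298,
                           heats = NULL) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            all(injection_volumes > 0), temperature > 0)
  if (!is.null(heats) && length(heats) != length(injection_volumes)) {
    stop("heats and injection_volumes differ in length", call. = FALSE)
  }
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 temperature = temperature, heats = heats),
            class = "itc_experiment")
}

# complex concentrations at equilibrium given free ligand L and totals
complex_concentrations <- function(l_free, p_tot, params) {
  if (params$model == "one_site") {
    pf <- p_tot / (1 + l_free / params$kd1)
    list(pl = pf * l_free / params$kd1, pl2 = 0)
  } else {
    k1 <- params$kd1; k2 <- params$kd2
    z <- 1 + l_free / k1 + l_free^2 / (k1 * k2)
    pf <- p_tot / z
    list(pl = pf * l_free / k1, pl2 = pf * l_free^2 / (k1 * k2))
  }
}

#' Free ligand concentration at equilibrium
#'
#' Solves the mass-balance polynomial of the one-site or sequential two-site
#' model for the free ligand concentration, by a bracketed monotone root
#' search polished with Newton steps; the relative mass-balance residual of
#' the returned root is below 1e-12.
#'
#' @param l_tot,p_tot Total ligand and protein concentrations (molar).
#' @param params A [binding_parameters()] object.
#' @return Free ligand concentration (molar) in `[0, l_tot]`.
#' @export
free_ligand <- function(l_tot, p_tot, params) {
  stopifnot(l_tot >= 0, p_tot >= 0)
  if (l_tot == 0) return(0)
  if (p_tot == 0) return(l_tot)
  # ligand tied up in complex: one_site -> pl; two_site -> pl + 2*pl2
  bound_of <- function(l) {
    cc <- complex_concentrations(l, p_tot, params)
    if (params$model == "one_site") cc$pl else cc$pl + 2 * cc$pl2
  }
  g <- function(l) l + bound_of(l) - l_tot       # strictly increasing in l
  if (params$model == "one_site") {
    # closed-form stable quadratic for the complex concentration
    s <- p_tot + l_tot + params$kd1
    c_pl <- 2 * p_tot * l_tot / (s + sqrt(s^2 - 4 * p_tot * l_tot))
    l <- l_tot - c_pl
    dg <- function(l) 1 + p_tot * params$kd1 / (params$kd1 + l)^2
  } else {
    # closed-form cubic mass balance in x = l / l_tot:
    # (x - 1)(1 + Tx/k1 + T^2 x^2/(k1 k2)) + (P/T)(Tx/k1 + 2 T^2 x^2/(k1 k2)) = 0
    k1 <- params$kd1; k2 <- params$kd2; tt <- l_tot; pp <- p_tot
    co <- c(-1,
            1 + (pp - tt) / k1,
            tt / k1 + (2 * pp - tt) * tt / (k1 * k2),
            tt^2 / (k1 * k2))
    rts <- polyroot(co)
    x <- Re(rts[abs(Im(rts)) < 1e-7 * (1 + abs(Re(rts))) &
                Re(rts) > -1e-12 & Re(rts) < 1 + 1e-12])
    if (length(x) == 0) {                         # fall back to bracketing
      l <- uniroot(g, lower = 0, upper = l_tot,
                   tol = max(1e-18, l_tot * 1e-13), maxiter = 200)$root
    } else {
      l <- min(max(min(x), 0), 1) * l_tot
    }
    dg <- function(l) {
      b <- l / k1 + 2 * l^2 / (k1 * k2)
      z <- 1 + l / k1 + l^2 / (k1 * k2)
      db <- 1 / k1 + 4 * l / (k1 * k2)
      dz <- 1 / k1 + 2 * l / (k1 * k2)
      1 + p_tot * (db * z - b * dz) / z^2
    }
  }
  # Newton polish against the exact mass balance
  for (it in 1:8) {
    r <- g(l)
    if (abs(r) <= 1e-14 * l_tot) break
    l_new <- l - r / dg(l)
    if (!is.finite(l_new) || l_new < 0 || l_new > l_tot) break
    l <- l_new
  }
  l
}

# running totals in the cell after each injection under the overflow
# (displaced volume) convention; concentrations referenced to cell volume
itc_totals <- function(exp, n = 1) {
  v0 <- exp$cell_volume
  m <- length(exp$injection_volumes)
  p <- numeric(m); l <- numeric(m); dil <- numeric(m)
  p_prev <- n * exp$cell_conc; l_prev <- 0
  for (i in seq_len(m)) {
    v <- exp$injection_volumes[i]
    d <- v0 / (v0 + v)
    p[i] <- p_prev * d
    l[i] <- l_prev * d + exp$syringe_conc * v / (v0 + v)
    dil[i] <- d
    p_prev <- p[i]; l_prev <- l[i]
  }
  list(p_tot = p, l_tot = l, dilution = dil)
}

#' Predicted injection heats of an ITC titration
#'
#' Forward model: after each injection the cell totals are updated under the
#' displaced-volume convention (pre-existing content diluted by
#' `V0/(V0+v)`, the expelled liquid carrying complex at its pre-injection
#' composition), the binding equilibrium is re-solved, and the measured heat
#' is the change in cell enthalpy content plus the dilution-heat offset:
#' `q_i = V0 * ([PL]_i*dH1 + [PL2]_i*(dH1+dH2) - d_i*([PL]_{i-1}*dH1 +
#' [PL2]_{i-1}*(dH1+dH2))) + q_dil`.
#'
#' @param params [binding_parameters()].
#' @param exp [itc_experiment()] (any `heats` present are ignored).
#' @return Numeric vector of predicted injection heats (J).
#' @export
itc_isotherm <- function(params, exp) {
  stopifnot(inherits(params, "binding_parameters"), inherits(exp, "itc_experiment"))
  v0 <- exp$cell_volume
  tot <- itc_totals(exp, n = params$n)
  m <- length(exp$injection_volumes)
  h_content <- function(p_tot, l_tot) {
    lf <- free_ligand(l_tot, p_tot, params)
    cc <- complex_concentrations(lf, p_tot, params)
    v0 * (cc$pl * params$dh1 +
            (if (params$model == "two_site") cc$pl2 * (params$dh1 + params$dh2) else 0))
  }
  heats <- numeric(m)
  h_prev <- 0
  for (i in seq_len(m)) {
    h_i <- h_content(tot$p_tot[i], tot$l_tot[i])
    heats[i] <- h_i - tot$dilution[i] * h_prev + params$q_dil
    h_prev <- h_i
  }
  heats
}

finite_diff_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, nrow = length(f0), ncol = length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' Fit one-site or two-site binding parameters to measured ITC heats
#'
#' Trust-region least squares (Levenberg-Marquardt) on `log10(Kd)`,
#' enthalpies in J/mol and the per-injection dilution offset, with
#' multi-start over a log-spaced Kd grid plus seeded jitter; the best
#' converged start by residual sum of squares is reported, together with
#' finite-difference standard errors and the Gibbs free-energy /
#' entropy decomposition at the experiment temperature
#' (`dG = RT ln Kd`, `TdS = dH - dG`).
#'
#' @param exp [itc_experiment()] carrying measured `heats`.
#' @param model `"one_site"` or `"two_site"`.
#' @param n_starts Number of multi-starts (default 8).
#' @param free_n Also fit the stoichiometry correction `n` (default `FALSE`,
#'   fixed at 1).
#' @param seed Integer seed controlling the start-point jitter.
#' @return Object of class `binding_fit`: `params` ([binding_parameters()]),
#'   `se` (named standard errors), `rss`, `dg1`, `dg2`, `tds1`, `tds2`
#'   (J/mol), `converged`, `n_injections`.
#' @export
fit_itc <- function(exp, model = c("one_site", "two_site"),
                    n_starts = 8, free_n = FALSE, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(exp, "itc_experiment"))
  heats <- exp$heats
  if (is.null(heats) || length(heats) < 10) {
    stop("fitting requires at least 10 injections with measured heats", call. = FALSE)
  }

  build_params <- function(par) {
    if (model == "one_site") {
      binding_parameters("one_site", kd1 = 10^par[1], dh1 = par[2],
                         n = if (free_n) par[4] else 1, q_dil = par[3])
    } else {
      binding_parameters("two_site", kd1 = 10^par[1], kd2 = 10^par[2],
                         dh1 = par[3], dh2 = par[4],
                         n = if (free_n) par[6] else 1, q_dil = par[5])
    }
  }
  resid_fn <- function(par) {
    p <- suppressWarnings(build_params(par))
    itc_isotherm(p, exp) - heats
  }

  # start values: dilution offset from the saturated tail, enthalpy scale
  # from the total heat evolved over the titratable protein
  q0 <- median(heats[max(1, length(heats) - 2):length(heats)])
  v0 <- exp$cell_volume
  ev <- if (model == "two_site") 2 else 1
  dh0 <- (sum(heats) - length(heats) * q0) / (v0 * exp$cell_conc * ev)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -4e4
  kd_grid <- 10^seq(log10(exp$cell_conc) - 3.5, log10(exp$cell_conc) + 1.5,
                    length.out = max(2, n_starts))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    k0 <- log10(kd_grid[((s - 1) %% length(kd_grid)) + 1]) + rnorm(1, 0, 0.15)
    par0 <- if (model == "one_site") {
      c(k0, dh0, q0, if (free_n) 1)
    } else {
      c(k0 - 0.5, k0 + 0.5, dh0, dh0, q0, if (free_n) 1)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("all fit starts failed", call. = FALSE)

  par <- best$fit$par
  params <- suppressWarnings(build_params(par))
  converged <- best$fit$info %in% 1:4

  # standard errors via the finite-difference Jacobian at the optimum
  m <- length(heats); p_n <- length(par)
  se_par <- rep(NA_real_, p_n)
  if (m > p_n) {
    J <- finite_diff_jacobian(resid_fn, par)
    sigma2 <- best$rss / (m - p_n)
    cv <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
    if (!is.null(cv)) se_par <- sqrt(pmax(diag(cv), 0))
  }
  ln10 <- log(10)
  if (model == "one_site") {
    se <- c(kd1 = params$kd1 * ln10 * se_par[1], dh1 = se_par[2], q_dil = se_par[3])
  } else {
    se <- c(kd1 = params$kd1 * ln10 * se_par[1], kd2 = params$kd2 * ln10 * se_par[2],
            dh1 = se_par[3], dh2 = se_par[4], q_dil = se_par[5])
  }

  rt <- .GAS_CONSTANT * exp$temperature
  dg1 <- rt * log(params$kd1)
  dg2 <- if (model == "two_site") rt * log(params$kd2) else NA_real_
  structure(list(params = params, se = se, rss = best$rss,
                 dg1 = dg1, dg2 = dg2,
                 tds1 = params$dh1 - dg1,
                 tds2 = if (model == "two_site") params$dh2 - dg2 else NA_real_,
                 temperature = exp$temperature,
                 converged = converged, n_injections = m),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  p <- x$params
  cat("<binding_fit> ", p$model, if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat(sprintf("  Kd1 = %.4g M (dG1 = %.2f kJ/mol, dH1 = %.2f, TdS1 = %.2f)\n",
              p$kd1, x$dg1 / 1e3, p$dh1 / 1e3, x$tds1 / 1e3))
  if (p$model == "two_site") {
    cat(sprintf("  Kd2 = %.4g M (dG2 = %.2f kJ/mol, dH2 = %.2f, TdS2 = %.2f)\n",
                p$kd2, x$dg2 / 1e3, p$dh2 / 1e3, x$tds2 / 1e3))
  }
  cat(sprintf("  rss = %.4g, %d injections\n", x$rss, x$n_injections))
  invisible(x)
}

#' Bound fraction of the limiting species at equilibrium
#'
#' Physically admissible root of `Kd * c = (p_tot - c)(r_tot - c)` expressed
#' as a fraction of the limiting total; inverse of the slow-exchange
#' peak-integral estimator, used for simulation and round trips.
#'
#' @param kd Dissociation constant (molar).
#' @param p_tot,r_tot Total protein and RNA concentrations (molar).
#' @return Bound fraction in (0, 1).
#' @export
bound_fraction_forward <- function(kd, p_tot, r_tot) {
  stopifnot(kd > 0, p_tot > 0, r_tot > 0)
  s <- p_tot + r_tot + kd
  cplx <- 2 * p_tot * r_tot / (s + sqrt(s^2 - 4 * p_tot * r_tot))
  cplx / min(p_tot, r_tot)
}

#' Dissociation constant from slow-exchange peak integrals
#'
#' In slow exchange the free and bound species give separate resonances whose
#' integrals report the bound fraction directly. For each resonance pair the
#' bound fraction `f = I_bound / (I_free + I_bound)` gives a complex
#' concentration `c = f * min(p_tot, r_tot)` and a dissociation constant
#' `Kd = (p_tot - c)(r_tot - c) / c`; estimates are aggregated as an
#' unweighted mean with the sample standard deviation across pairs.
#'
#' @param pairs Data frame with columns `resonance_id`, `i_free`, `i_bound`
#'   (non-negative peak integrals, not both zero).
#' @param p_tot,r_tot Total protein and RNA concentrations (molar).
#' @return Object of class `kd_estimate`: `kd_mean`, `kd_sd`, `n_pairs`,
#'   `p_tot`, `r_tot`, `per_pair` (data frame with `f_bound` and `kd`),
#'   `flags`.
#' @export
kd_from_integrals <- function(pairs, p_tot, r_tot) {
  stopifnot(p_tot > 0, r_tot > 0)
  req <- c("resonance_id", "i_free", "i_bound")
  if (!all(req %in% names(pairs))) {
    stop("integral table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pairs) < 1) stop("at least one resonance pair required", call. = FALSE)
  if (any(pairs$i_free < 0 | pairs$i_bound < 0) ||
      any(pairs$i_free + pairs$i_bound == 0)) {
    stop("integrals must be non-negative and not both zero", call. = FALSE)
  }
  f <- pairs$i_bound / (pairs$i_free + pairs$i_bound)
  if (any(f == 0 | f == 1)) {
    stop("bound fraction of 0 or 1: outside the slow-exchange quantifiable range",
         call. = FALSE)
  }
  cplx <- f * min(p_tot, r_tot)
  kd <- (p_tot - cplx) * (r_tot - cplx) / cplx
  flags <- character(0)
  if (nrow(pairs) == 1L) flags <- "single_pair_no_spread"
  structure(list(kd_mean = mean(kd),
                 kd_sd = if (nrow(pairs) > 1L) sd(kd) else 0,
                 n_pairs = nrow(pairs), p_tot = p_tot, r_tot = r_tot,
                 per_pair = data.frame(resonance_id = pairs$resonance_id,
                                       f_bound = f, kd = kd,
                                       stringsAsFactors = FALSE),
                 flags = flags),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("<kd_estimate> Kd = %.4g +/- %.2g M (%d resonance pair%s)\n",
              x$kd_mean, x$kd_sd, x$n_pairs, if (x$n_pairs == 1) "" else "s"))
  invisible(x)
}
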