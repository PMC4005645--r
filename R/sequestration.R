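# ---- Equilibrium sequestration of protein sites by RNA motif pools ---------
#
# Independent-site approximation: every GGA motif is an independent ligand
# competing for identical protein binding sites (two per homodimer).

#' A pool of identical GGA-motif sites competing for the protein
#'
#' @param name Pool identifier.
#' @param kd Per-site dissociation constant (molar). Alternatively supply
#'   `tier` and the geometric mean of that tier's range is used
#'   ([tier_kd()]).
#' @param site_conc Total concentration of this motif site (molar).
#' @param role `"rbs"` (the mRNA ribosome-binding site whose occupancy
#'   represses translation), `"decoy"` (a sequestering sRNA motif) or
#'   `"other"`.
#' @param tier Optional tier label used when `kd` is missing.
#' @return Object of class `ligand_pool`.
#' @export
ligand_pool <- function(name, kd = NULL, site_conc,
                        role = c("other", "rbs", "decoy"), tier = NULL) {
  role <- match.arg(role)
  if (is.null(kd)) {
    if (is.null(tier)) stop("supply kd or tier for pool ", sQuote(name), call. = FALSE)
    kd <- tier_kd(tier)
  }
  stopifnot(kd > 0, site_conc >= 0)
  structure(list(name = name, kd = kd, site_conc = site_conc, role = role,
                 tier = tier),
            class = "ligand_pool")
}

#' Solve for the free protein-site concentration
#'
#' Finds the unique root S of `S + sum_j M_j * S / (kd_j + S) = S_tot` on
#' `(0, S_tot)` by bracketed monotone root-finding with Newton polish;
#' the relative mass-balance residual is below 1e-12.
#'
#' @param pools List of [ligand_pool()] objects.
#' @param protein_dimer_conc Total protein homodimer concentration (molar);
#'   contributes two sites per dimer.
#' @param site_total Total site concentration (molar); defaults to
#'   `2 * protein_dimer_conc`.
#' @return Free site concentration (molar).
#' @export
solve_free_sites <- function(pools, protein_dimer_conc = NULL,
                             site_total = 2 * protein_dimer_conc) {
  stopifnot(length(pools) >= 0, site_total >= 0)
  if (site_total == 0) return(0)
  m <- vapply(pools, function(p) p$site_conc, numeric(1))
  kd <- vapply(pools, function(p) p$kd, numeric(1))
  if (length(m) == 0 || sum(m) == 0) return(site_total)
  g <- function(s) s + sum(m * s / (kd + s)) - site_total
  s <- uniroot(g, lower = 0, upper = site_total,
               tol = max(1e-18, site_total * 1e-13), maxiter = 200)$root
  for (it in 1:8) {
    r <- g(s)
    if (abs(r) <= 1e-13 * site_total) break
    dr <- 1 + sum(m * kd / (kd + s)^2)
    s_new <- s - r / dr
    if (!is.finite(s_new) || s_new < 0 || s_new > site_total) break
    s <- s_new
  }
  s
}

#' Fractional occupancy of a ligand site at a given free-site concentration
#'
#' Standard single-site isotherm `theta = S / (kd + S)`.
#'
#' @param kd Site dissociation constant (molar).
#' @param free_site Free protein-site concentration (molar).
#' @return Occupancy in `[0, 1)`.
#' @export
occupancy <- function(kd, free_site) {
  stopifnot(kd > 0, free_site >= 0)
  free_site / (kd + free_site)
}

#' Solve a sequestration system and report per-pool occupancies
#'
#' @inheritParams solve_free_sites
#' @return List with `free_site` (molar), `site_total` and a data frame
#'   `pools` (`name`, `kd`, `site_conc`, `role`, `theta`, `bound`).
#' @export
solve_system <- function(pools, protein_dimer_conc = NULL,
                         site_total = 2 * protein_dimer_conc) {
  s <- solve_free_sites(pools, site_total = site_total)
  tab <- do.call(rbind, lapply(pools, function(p) {
    th <- occupancy(p$kd, s)
    data.frame(name = p$name, kd = p$kd, site_conc = p$site_conc,
               role = p$role, theta = th, bound = th * p$site_conc,
               stringsAsFactors = FALSE)
  }))
  list(free_site = s, site_total = site_total, pools = tab)
}

#' Translation de-repression as a function of sRNA concentration
#'
#' The mRNA ribosome-binding site is repressed in proportion to its protein
#' occupancy; decoy sRNA motifs titrate protein sites away. For each sRNA
#' concentration on the grid, the decoy pool site concentrations are scaled
#' (each decoy's `site_conc` is interpreted as sites per sRNA molecule),
#' the competition equilibrium is solved, and translation activity
#' `1 - theta_rbs` is reported, normalized to the grid maximum — mirroring
#' reporter assays normalized to their largest expression value.
#'
#' @param mrna_rbs [ligand_pool()] with `role = "rbs"`.
#' @param srna_pools List of decoy [ligand_pool()]s; their `site_conc` is
#'   per-sRNA site multiplicity (usually 1 per motif).
#' @param protein_dimer_conc Total dimer concentration (molar).
#' @param srna_conc_grid Vector of total sRNA concentrations (molar).
#' @return Data frame with `srna_conc`, `free_site`, `theta_rbs`,
#'   `activity_raw` (`1 - theta_rbs`) and `activity` (normalized).
#' @export
derepression_curve <- function(mrna_rbs, srna_pools, protein_dimer_conc,
                               srna_conc_grid) {
  stopifnot(inherits(mrna_rbs, "ligand_pool"))
  if (!identical(mrna_rbs$role, "rbs")) stop("mrna_rbs must have role 'rbs'", call. = FALSE)
  if (length(srna_conc_grid) == 0) stop("empty sRNA concentration grid", call. = FALSE)
  rows <- lapply(srna_conc_grid, function(cs) {
    scaled <- lapply(srna_pools, function(p) {
      p$site_conc <- p$site_conc * cs
      p
    })
    sol <- solve_system(c(list(mrna_rbs), scaled),
                        protein_dimer_conc = protein_dimer_conc)
    th <- sol$pools$theta[sol$pools$role == "rbs"][1]
    data.frame(srna_conc = cs, free_site = sol$free_site, theta_rbs = th,
               activity_raw = 1 - th)
  })
  out <- do.call(rbind, rows)
  out$activity <- out$activity_raw / max(out$activity_raw)
  out
}

#' Rank sRNA site-knockout mutants by translation activation
#'
#' Each mutation removes one decoy pool (the binding-abolished motif,
#' equivalent to `kd -> Inf`); activities are evaluated at a fixed sRNA and
#' protein concentration and returned in decreasing order, wild type
#' included.
#'
#' @param mrna_rbs [ligand_pool()] with `role = "rbs"`.
#' @param base_pools Decoy pools of the wild-type sRNA (per-sRNA site
#'   multiplicities as in [derepression_curve()]).
#' @param mutations Character vector of pool names to knock out, one scenario
#'   per element (`"wt"` is always included automatically).
#' @param srna_conc Total sRNA concentration (molar).
#' @param protein_dimer_conc Total dimer concentration (molar).
#' @return Data frame `scenario`, `activity_raw`, `activity` (normalized to
#'   the scenario maximum), sorted by decreasing activity; ties keep input
#'   order.
#' @export
rank_mutants <- function(mrna_rbs, base_pools, mutations, srna_conc,
                         protein_dimer_conc) {
  pool_names <- vapply(base_pools, function(p) p$name, character(1))
  missing <- setdiff(mutations, pool_names)
  if (length(missing)) {
    stop("unknown site name(s) in mutations: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  activity_of <- function(pools) {
    derepression_curve(mrna_rbs, pools, protein_dimer_conc,
                       srna_conc_grid = srna_conc)$activity_raw[1]
  }
  scen <- c("wt", mutations)
  act <- vapply(scen, function(sc) {
    pools <- if (sc == "wt") base_pools else base_pools[pool_names != sc]
    activity_of(pools)
  }, numeric(1))
  out <- data.frame(scenario = scen, activity_raw = unname(act),
                    stringsAsFactors = FALSE)
  out$activity <- out$activity_raw / max(out$activity_raw)
  out[order(-out$activity_raw), , drop = FALSE]
}

#' Sequential site occupancy along a protein titration
#'
#' For motif sites on one RNA, evaluates per-site occupancy across a grid of
#' protein-dimer : RNA equivalents and reports the first equivalence point at
#' which each site exceeds half occupancy — tighter sites saturate at lower
#' protein equivalents, reproducing the appearance order of site-specific
#' resonances in a protein-into-RNA NMR titration.
#'
#' @param site_pools List of [ligand_pool()]s, ordered by position on the
#'   RNA; their `site_conc` must equal the RNA concentration (one site of
#'   each kind per molecule).
#' @param rna_conc Total RNA concentration (molar).
#' @param equivalents Grid of dimer:RNA ratios.
#' @return List with `occupancy` (data frame: `equivalents`, one `theta_*`
#'   column per site) and `half_saturation` (data frame: `name`,
#'   `equivalents_at_half`, `NA` if never reached).
#' @export
sequential_occupancy <- function(site_pools, rna_conc,
                                 equivalents = seq(0.1, 3, by = 0.1)) {
  stopifnot(rna_conc > 0, length(equivalents) > 0)
  names_ <- vapply(site_pools, function(p) p$name, character(1))
  occ <- t(vapply(equivalents, function(ev) {
    sol <- solve_system(site_pools, protein_dimer_conc = ev * rna_conc)
    sol$pools$theta
  }, numeric(length(site_pools))))
  occ <- matrix(occ, nrow = length(equivalents))
  colnames(occ) <- paste0("theta_", names_)
  half <- vapply(seq_along(site_pools), function(j) {
    i <- which(occ[, j] > 0.5)
    if (length(i)) equivalents[min(i)] else NA_real_
  }, numeric(1))
  list(occupancy = data.frame(equivalents = equivalents, occ,
                              check.names = FALSE),
       half_saturation = data.frame(name = names_, equivalents_at_half = half,
                                    stringsAsFactors = FALSE))
}
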