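# ---- File-level pipeline commands and format plumbing ----------------------
#
# These functions are the package's command surface; inst/cli/ggaffinity.R is
# a thin shell dispatcher over them. All numeric outputs are in molar, J/mol
# and K in machine-readable files; human summaries auto-scale Kd to nM/uM/mM.

UCAL_TO_J <- 4.184e-6

format_kd <- function(kd) {
  ifelse(kd < 1e-6, sprintf("%.3g nM", kd * 1e9),
         ifelse(kd < 1e-3, sprintf("%.3g uM", kd * 1e6),
                sprintf("%.3g mM", kd * 1e3)))
}

# rolling polynomial hash over the deparsed config; provenance stamp
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance <- function(config = list()) {
  list(package = "ggaffinity",
       version = as.character(utils::packageVersion("ggaffinity")),
       config_hash = config_hash(config))
}

#' Scan a Vienna file for GGA motifs and write a report
#'
#' @param input Path to a multi-record Vienna dot-bracket file.
#' @param tsv Optional output TSV path (1-based inclusive coordinates).
#' @param json Optional output JSON path (same content plus per-tier counts
#'   and a provenance block).
#' @return Invisibly, the motif table ([motif_report_table()]) with the list
#'   of `motif_report`s in attribute `"reports"`.
#' @export
gga_scan_file <- function(input, tsv = NULL, json = NULL) {
  mols <- read_vienna(input)
  reports <- lapply(mols, scan_motifs)
  tab <- motif_report_table(reports)
  counts <- Reduce(`+`, lapply(reports, function(r) r$tier_counts))
  if (!is.null(tsv)) {
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(provenance = provenance(list(input = basename(input))),
           motifs = tab, tier_counts = as.list(counts)),
      json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  attr(tab, "reports") <- reports
  invisible(tab)
}

read_thermogram_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"injection_index" %in% names(tab) || !"volume_ul" %in% names(tab)) {
    stop("thermogram CSV must have columns injection_index, volume_ul and ",
         "heat_ucal or heat_J", call. = FALSE)
  }
  heats <- if ("heat_J" %in% names(tab)) {
    tab$heat_J
  } else if ("heat_ucal" %in% names(tab)) {
    tab$heat_ucal * UCAL_TO_J
  } else {
    stop("no heat column (heat_ucal or heat_J) in ", path, call. = FALSE)
  }
  tab <- tab[order(tab$injection_index), ]
  list(volumes = tab$volume_ul * 1e-6, heats = heats[order(tab$injection_index)])
}

#' Fit a binding model to an ITC thermogram file
#'
#' @param csv Thermogram CSV with columns `injection_index`, `volume_ul` and
#'   `heat_ucal` or `heat_J` (the column name carries the unit).
#' @param model `"one_site"` or `"two_site"`.
#' @param cell_volume,cell_conc,syringe_conc,temperature Experiment metadata
#'   (litres, molar, molar, Kelvin).
#' @param json Optional output path for the fit report.
#' @param residuals_tsv Optional output path for per-injection residuals.
#' @param seed Multi-start jitter seed.
#' @return The [fit_itc()] result, invisibly.
#' @export
itc_fit_file <- function(csv, model = c("one_site", "two_site"),
                         cell_volume, cell_conc, syringe_conc,
                         temperature = 298, json = NULL,
                         residuals_tsv = NULL, seed = 1) {
  model <- match.arg(model)
  tg <- read_thermogram_csv(csv)
  if (length(tg$heats) < 10) {
    stop("thermogram has fewer than 10 injections", call. = FALSE)
  }
  exp <- itc_experiment(cell_volume, cell_conc, syringe_conc, tg$volumes,
                        temperature, heats = tg$heats)
  fit <- fit_itc(exp, model = model, seed = seed)
  pred <- itc_isotherm(fit$params, exp)
  if (!is.null(residuals_tsv)) {
    write.table(data.frame(injection_index = seq_along(pred),
                           heat_J = tg$heats, predicted_J = pred,
                           residual_J = tg$heats - pred),
                residuals_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    p <- fit$params
    jsonlite::write_json(list(
      provenance = provenance(list(csv = basename(csv), model = model)),
      model = model, converged = fit$converged,
      kd1_M = p$kd1, kd2_M = p$kd2, dh1_J_mol = p$dh1, dh2_J_mol = p$dh2,
      q_dil_J = p$q_dil, se = as.list(fit$se), rss = fit$rss,
      dg1_J_mol = fit$dg1, dg2_J_mol = fit$dg2,
      tds1_J_mol = fit$tds1, tds2_J_mol = fit$tds2,
      temperature_K = exp$temperature
    ), json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(fit)
}

#' Estimate Kd from an NMR integral-pair file
#'
#' @param csv CSV with columns `resonance_id`, `i_free`, `i_bound`.
#' @param p_tot,r_tot Total protein and RNA concentrations (molar).
#' @param json Optional output path.
#' @return The [kd_from_integrals()] result, invisibly.
#' @export
nmr_kd_file <- function(csv, p_tot, r_tot, json = NULL) {
  tab <- read.csv(csv, stringsAsFactors = FALSE)
  est <- kd_from_integrals(tab, p_tot, r_tot)
  if (!is.null(json)) {
    jsonlite::write_json(list(
      provenance = provenance(list(csv = basename(csv))),
      kd_mean_M = est$kd_mean, kd_sd_M = est$kd_sd, n_pairs = est$n_pairs,
      p_tot_M = p_tot, r_tot_M = r_tot,
      per_pair = est$per_pair, flags = est$flags
    ), json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(est)
}

pool_from_config <- function(cfg, role_default = "decoy") {
  ligand_pool(name = cfg$name,
              kd = if (!is.null(cfg$kd)) cfg$kd else NULL,
              tier = if (!is.null(cfg$tier)) cfg$tier else NULL,
              site_conc = if (!is.null(cfg$site_conc)) cfg$site_conc else 1,
              role = if (!is.null(cfg$role)) cfg$role else role_default)
}

#' Run a sequestration/competition scenario from a JSON config
#'
#' The scenario JSON has `protein_dimer_conc` (molar), an `rbs` pool
#' (`name`, `kd` or `tier`, `site_conc`), `decoys` (list of pools;
#' `site_conc` is sites per sRNA molecule), and either `srna_conc_grid`
#' (de-repression curve, with optional `mutations` for knockout ranking at
#' `srna_conc`) or `mode = "sequential"` with `rna_conc` and `equivalents`.
#'
#' @param scenario Path to the scenario JSON.
#' @param tsv Optional output TSV (curve or occupancy table).
#' @return Invisibly, a list with the computed tables.
#' @export
compete_file <- function(scenario, tsv = NULL) {
  cfg <- jsonlite::read_json(scenario, simplifyVector = FALSE)
  if (identical(cfg$mode, "sequential")) {
    pools <- lapply(cfg$sites, function(p) {
      p$site_conc <- cfg$rna_conc
      pool_from_config(p, role_default = "other")
    })
    res <- sequential_occupancy(pools, rna_conc = cfg$rna_conc,
                                equivalents = unlist(cfg$equivalents))
    if (!is.null(tsv)) {
      write.table(res$occupancy, tsv, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    return(invisible(res))
  }
  rbs <- pool_from_config(cfg$rbs, role_default = "rbs")
  decoys <- lapply(cfg$decoys, pool_from_config)
  grid <- unlist(cfg$srna_conc_grid)
  curve <- derepression_curve(rbs, decoys, cfg$protein_dimer_conc, grid)
  out <- list(curve = curve)
  if (!is.null(cfg$mutations)) {
    out$ranking <- rank_mutants(rbs, decoys, unlist(cfg$mutations),
                                srna_conc = cfg$srna_conc,
                                protein_dimer_conc = cfg$protein_dimer_conc)
  }
  if (!is.null(tsv)) {
    write.table(curve, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Generate a named fixture and write it to disk
#'
#' RNA presets are written as Vienna records; the calorimetry preset as a
#' thermogram CSV (`heat_ucal` column); NMR presets as integral-pair CSVs.
#'
#' @param name Preset name (see [fixture_preset()]).
#' @param out Output path.
#' @param seed Integer seed.
#' @return The output path, invisibly.
#' @export
simulate_fixture <- function(name, out, seed = 1) {
  fx <- fixture_preset(name, seed = seed)
  if (name %in% c("sl2_like", "pentaloop_no_n", "ss9_like", "buried_gga")) {
    write_vienna(fx$molecule, out)
  } else if (name == "sl2_itc") {
    exp <- make_itc(fx$params, fx$design, seed = seed)
    write.csv(data.frame(injection_index = seq_along(exp$heats),
                         volume_ul = exp$injection_volumes * 1e6,
                         heat_ucal = exp$heats / UCAL_TO_J),
              out, row.names = FALSE, quote = FALSE)
  } else {
    write.csv(fx$pairs, out, row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}
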