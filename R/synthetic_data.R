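# ---- Seeded synthetic generators -------------------------------------------
#
# Generators are pure functions of (spec, seed): the caller's RNG state is
# saved and restored, so the same seed always yields byte-identical output.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

# random helix 5' strand: 60% GC, never ending in the bases supplied in
# `avoid_suffix` adjacent positions is handled by fixed closing pairs instead
sample_stem5 <- function(n) {
  if (n <= 0) return(character(0))
  sample(c("G", "C", "A", "U"), n, replace = TRUE,
         prob = c(0.3, 0.3, 0.2, 0.2))
}

# unpaired filler from {A, C, U}: cannot create a spurious GGA
sample_filler <- function(n) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "U"), n, replace = TRUE)
}

#' Generate an RNA molecule with a planted GGA motif of a given context
#'
#' Emulates the benchmark construct geometry: a hairpin whose loop carries the
#' A(N)GGA(X) element on a complementary Watson-Crick stem (closing pair C-G,
#' penultimate U-A, like the measured constructs), a single-stranded motif, or
#' a motif partially/fully buried in a helix. Stems are sampled at 60% GC;
#' unpaired filler is drawn from {A, C, U} so no spurious GGA can arise there.
#'
#' @param context Target context class (one of the seven framework classes).
#' @param n_base,x_base Identities of the looped-out N and the 3' X where the
#'   class has them.
#' @param stem_length Stacked pairs supporting the loop (>= 2 for loop
#'   classes).
#' @param inserted Inserted nucleotides between the element and the stem
#'   (EXPANDED_LOOP only, 1-4 from {C, U}).
#' @param n_buried For PARTIALLY_PAIRED, how many of the G,G,A bases are in
#'   the helix (1 or 2).
#' @param flank Unpaired filler length on each side of the hairpin.
#' @param name Record name; a default is derived from the context.
#' @param seed Integer seed.
#' @return List with `molecule` ([rna_molecule()]), `context` (the planted
#'   class), `gga_start` (0-based position of the planted GGA) and
#'   `loop_span` (0-based half-open, `NA` for non-loop classes).
#' @export
make_rna_with_motif <- function(context, n_base = "C", x_base = "U",
                                stem_length = 4L, inserted = 2L,
                                n_buried = 2L, flank = 3L,
                                name = NULL, seed = 1) {
  stopifnot(context %in% CONTEXT_CLASSES)
  if (is.null(name)) name <- paste0(tolower(context), "_s", seed)
  with_local_seed(seed, {
    loop_classes <- c("HEXALOOP_ON_STEM", "PURINE_PENTALOOP", "PENTALOOP_NO_N",
                      "EXPANDED_LOOP")
    if (context %in% loop_classes) {
      if (stem_length < 2L) {
        stop("loop contexts require stem_length >= 2 (a loop on a single pair ",
             "is not 'on top of a stem')", call. = FALSE)
      }
      loop <- switch(context,
        HEXALOOP_ON_STEM = c("A", n_base, "G", "G", "A", x_base),
        PURINE_PENTALOOP = {
          if (!n_base %in% c("A", "G")) {
            stop("PURINE_PENTALOOP requires a purine N", call. = FALSE)
          }
          c("A", n_base, "G", "G", "A")
        },
        PENTALOOP_NO_N = c("A", "G", "G", "A", x_base),
        EXPANDED_LOOP = {
          if (inserted < 1L) stop("EXPANDED_LOOP requires inserted >= 1", call. = FALSE)
          c("A", n_base, "G", "G", "A", x_base,
            sample(c("C", "U"), inserted, replace = TRUE))
        })
      gga_in_loop <- if (context == "PENTALOOP_NO_N") 1L else 2L  # first G offset in loop
      # stem 5' strand, closing pair C-G with penultimate U-A underneath
      stem5 <- c(sample_stem5(stem_length - 2L), "U", "C")
      stem3 <- rev(unname(WC_PARTNER[stem5]))
      f5 <- sample_filler(flank); f3 <- sample_filler(flank)
      seq <- c(f5, stem5, loop, stem3, f3)
      struct <- c(rep(".", length(f5)), rep("(", stem_length),
                  rep(".", length(loop)), rep(")", stem_length),
                  rep(".", length(f3)))
      gga_start <- length(f5) + stem_length + gga_in_loop
      loop_span <- c(length(f5) + stem_length,
                     length(f5) + stem_length + length(loop))
    } else if (context == "SINGLE_STRANDED") {
      core <- if (is.na(n_base) || is.null(n_base)) c("A", "G", "G", "A")
              else c("A", n_base, "G", "G", "A")
      f5 <- sample_filler(flank); f3 <- sample_filler(flank)
      seq <- c(f5, core, f3)
      struct <- rep(".", length(seq))
      gga_start <- length(f5) + length(core) - 3L
      loop_span <- c(NA_integer_, NA_integer_)
    } else if (context == "PARTIALLY_PAIRED") {
      if (!n_buried %in% 1:2) stop("n_buried must be 1 or 2", call. = FALSE)
      # last n_buried stem bases are G(s); the rest of the GGA sits in the loop
      stem5 <- c(sample_stem5(stem_length - n_buried),
                 rep("G", n_buried))
      stem3 <- rev(unname(WC_PARTNER[stem5]))
      loop <- if (n_buried == 2L) c("A", sample(c("C", "U"), 3, replace = TRUE))
              else c("G", "A", sample(c("C", "U"), 2, replace = TRUE))
      f5 <- sample_filler(flank); f3 <- sample_filler(flank)
      seq <- c(f5, stem5, loop, stem3, f3)
      struct <- c(rep(".", length(f5)), rep("(", stem_length),
                  rep(".", length(loop)), rep(")", stem_length),
                  rep(".", length(f3)))
      gga_start <- length(f5) + stem_length - n_buried
      loop_span <- c(NA_integer_, NA_integer_)
    } else { # FULLY_PAIRED
      if (stem_length < 5L) stem_length <- 5L
      mid <- stem_length %/% 2 - 1L
      stem5 <- sample_stem5(stem_length)
      stem5[mid + 1:3] <- c("G", "G", "A")
      stem3 <- rev(unname(WC_PARTNER[stem5]))
      loop <- sample(c("C", "U"), 4, replace = TRUE)
      f5 <- sample_filler(flank); f3 <- sample_filler(flank)
      seq <- c(f5, stem5, loop, stem3, f3)
      struct <- c(rep(".", length(f5)), rep("(", stem_length),
                  rep(".", length(loop)), rep(")", stem_length),
                  rep(".", length(f3)))
      gga_start <- length(f5) + mid
      loop_span <- c(NA_integer_, NA_integer_)
    }
    mol <- rna_molecule(name, paste(seq, collapse = ""),
                        paste(struct, collapse = ""))
    list(molecule = mol, context = context, gga_start = gga_start,
         loop_span = loop_span)
  })
}

#' Titration design for simulated calorimetry
#'
#' Defaults follow typical protein-RNA titrations: 35 injections of 8 ul
#' from a syringe at 300 uM into a 1.4 ml cell at 10 uM dimer, 298 K.
#'
#' @param n_injections Number of injections.
#' @param injection_volume Per-injection volume (litres).
#' @param cell_volume Cell volume (litres).
#' @param cell_conc Cell protein (dimer) concentration (molar).
#' @param syringe_conc Syringe RNA concentration (molar).
#' @param temperature Kelvin.
#' @return Object of class `itc_design`.
#' @export
itc_design <- function(n_injections = 35L, injection_volume = 8e-6,
                       cell_volume = 1.4e-3, cell_conc = 10e-6,
                       syringe_conc = 300e-6, temperature = 298) {
  structure(list(n_injections = as.integer(n_injections),
                 injection_volume = injection_volume,
                 cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, temperature = temperature),
            class = "itc_design")
}

#' Simulate a noisy ITC experiment
#'
#' Heats are the forward-model isotherm plus additive Gaussian noise
#' (instrument-like); the noise standard deviation is either given in joules
#' or as a fraction of the full-scale (largest-magnitude) clean heat.
#'
#' @param params [binding_parameters()].
#' @param design [itc_design()].
#' @param noise_sd Noise standard deviation (J); overrides `noise_frac`.
#' @param noise_frac Noise standard deviation as a fraction of
#'   `max(abs(clean heats))` (default 0.01).
#' @param seed Integer seed.
#' @return [itc_experiment()] with `heats` filled; attribute `"clean_heats"`
#'   holds the noise-free curve.
#' @export
make_itc <- function(params, design, noise_sd = NULL, noise_frac = 0.01,
                     seed = 1) {
  stopifnot(inherits(design, "itc_design"))
  exp <- itc_experiment(cell_volume = design$cell_volume,
                        cell_conc = design$cell_conc,
                        syringe_conc = design$syringe_conc,
                        injection_volumes = rep(design$injection_volume,
                                                design$n_injections),
                        temperature = design$temperature)
  clean <- itc_isotherm(params, exp)
  if (is.null(noise_sd)) noise_sd <- noise_frac * max(abs(clean))
  exp$heats <- with_local_seed(seed, clean + rnorm(length(clean), 0, noise_sd))
  attr(exp, "clean_heats") <- clean
  attr(exp, "noise_sd") <- noise_sd
  exp
}

#' Simulate slow-exchange free/bound resonance integral pairs
#'
#' The bound fraction follows from the mass-balance quadratic
#' ([bound_fraction_forward()]); each resonance contributes integrals
#' proportional to `(1 - f, f)` with multiplicative lognormal noise of
#' coefficient of variation `noise_cv` per peak (peak-integration-like).
#'
#' @param kd Dissociation constant (molar).
#' @param p_tot,r_tot Total protein and RNA concentrations (molar).
#' @param n_pairs Number of resonance pairs.
#' @param noise_cv Per-peak coefficient of variation (0 = noise-free).
#' @param seed Integer seed.
#' @return Data frame `resonance_id`, `i_free`, `i_bound`.
#' @export
make_integral_pairs <- function(kd, p_tot, r_tot, n_pairs = 6L,
                                noise_cv = 0, seed = 1) {
  stopifnot(n_pairs >= 1)
  f <- bound_fraction_forward(kd, p_tot, r_tot)
  with_local_seed(seed, {
    noise <- function(n) {
      if (noise_cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    data.frame(resonance_id = paste0("res", seq_len(n_pairs)),
               i_free = (1 - f) * noise(n_pairs),
               i_bound = f * noise(n_pairs),
               stringsAsFactors = FALSE)
  })
}

#' Named fixture presets mirroring the benchmark constructs
#'
#' * `sl2_like`: ACGGAU hexaloop on a 4-pair stem (high-affinity geometry).
#' * `pentaloop_no_n`: AGGAU pentaloop on a stem (N missing).
#' * `ss9_like`: 9-nt single-stranded AGGA-carrying RNA.
#' * `buried_gga`: GGA fully inside a helix.
#' * `sl2_itc`: two-site titration preset — the packaged SL2 reference
#'   constants (Kd 16 nM and 185 nM) with enthalpies -90 and -70 kJ/mol and a
#'   small dilution offset, under the default [itc_design()].
#' * `hcn_gga2_nmr` / `hcn_gga1_nmr`: slow-exchange integral-pair presets at
#'   0.54 mM protein and RNA totals with the packaged reference constants
#'   (2.7 mM and 300 uM).
#'
#' @param name Preset name.
#' @param seed Integer seed forwarded to the generator.
#' @return The generated object (see the individual generators).
#' @export
fixture_preset <- function(name, seed = 1) {
  switch(name,
    sl2_like = make_rna_with_motif("HEXALOOP_ON_STEM", n_base = "C",
                                   x_base = "U", stem_length = 4L, seed = seed),
    pentaloop_no_n = make_rna_with_motif("PENTALOOP_NO_N", x_base = "U",
                                         stem_length = 4L, seed = seed),
    ss9_like = make_rna_with_motif("SINGLE_STRANDED", n_base = NA,
                                   flank = 3L, seed = seed),
    buried_gga = make_rna_with_motif("FULLY_PAIRED", stem_length = 6L,
                                     seed = seed),
    sl2_itc = {
      ref <- reference_table()
      sl2 <- ref[ref$rna_name == "SL2", ]
      list(params = binding_parameters("two_site", kd1 = sl2$kd1,
                                       kd2 = sl2$kd2, dh1 = -90e3, dh2 = -70e3,
                                       q_dil = -5e-7),
           design = itc_design())
    },
    hcn_gga2_nmr = {
      ref <- reference_table()
      kd <- ref$kd1[ref$rna_name == "hcnA-GGA#2"]
      list(kd = kd, p_tot = 5.4e-4, r_tot = 5.4e-4,
           pairs = make_integral_pairs(kd, 5.4e-4, 5.4e-4, n_pairs = 6L,
                                       noise_cv = 0, seed = seed))
    },
    hcn_gga1_nmr = {
      ref <- reference_table()
      kd <- ref$kd1[ref$rna_name == "hcnA-GGA#1"]
      list(kd = kd, p_tot = 5.4e-4, r_tot = 5.4e-4,
           pairs = make_integral_pairs(kd, 5.4e-4, 5.4e-4, n_pairs = 6L,
                                       noise_cv = 0, seed = seed))
    },
    stop("unknown preset: ", name, call. = FALSE)
  )
}
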