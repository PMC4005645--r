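# ---- GGA motif location, context classification and affinity tiers ---------

CONTEXT_CLASSES <- c("HEXALOOP_ON_STEM", "PURINE_PENTALOOP", "PENTALOOP_NO_N",
                     "EXPANDED_LOOP", "SINGLE_STRANDED", "PARTIALLY_PAIRED",
                     "FULLY_PAIRED")

TIER_LEVELS <- c("HIGH", "INTERMEDIATE", "INTERMEDIATE_LOW", "LOW", "VERY_LOW")

#' Dissociation-constant tier table
#'
#' The discrete affinity classes used by the prediction framework, each with a
#' calibrated molar dissociation-constant range. The ranges are disjoint,
#' ordered, and jointly span more than five orders of magnitude — from the
#' strongest measured hexaloop motifs (~10 nM scale) down to fully base-paired
#' motifs (~3 mM scale).
#'
#' @return Data frame with columns `tier`, `kd_lower`, `kd_upper` (molar).
#' @export
tier_table <- function() {
  data.frame(
    tier = factor(TIER_LEVELS, levels = TIER_LEVELS),
    kd_lower = c(5e-9, 5e-7, 1e-5, 1e-4, 1e-3),
    kd_upper = c(5e-7, 1e-5, 1e-4, 1e-3, 1e-2),
    stringsAsFactors = FALSE
  )
}

tier_bounds <- function(tier) {
  tt <- tier_table()
  tt[match(tier, as.character(tt$tier)), c("kd_lower", "kd_upper")]
}

#' Geometric-mean point dissociation constant for a tier
#'
#' Used when equilibrium arithmetic needs a point value for a motif known only
#' by tier (e.g. sequestration scenarios).
#'
#' @param tier Tier label (`"HIGH"`, ..., `"VERY_LOW"`).
#' @return Molar dissociation constant.
#' @export
tier_kd <- function(tier) {
  b <- tier_bounds(tier)
  if (anyNA(b$kd_lower)) stop("unknown tier: ", paste(tier, collapse = ", "), call. = FALSE)
  sqrt(b$kd_lower * b$kd_upper)
}

#' Locate GGA trinucleotides
#'
#' Every occurrence of the trinucleotide GGA, in order; overlapping
#' occurrences are all reported (deduplication by the anchor rule happens in
#' [scan_motifs()]).
#'
#' @param rna An [rna_molecule()].
#' @return Integer vector of 0-based start positions (possibly empty).
#' @export
find_gga <- function(rna) {
  stopifnot(inherits(rna, "rna_molecule"))
  hits <- gregexpr("(?=GGA)", rna$sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

base_at <- function(rna, i) {
  if (i < 0L || i >= rna$length) return(NA_character_)
  substr(rna$sequence, i + 1L, i + 1L)
}

#' Classify the sequence/structural context of one GGA motif
#'
#' Applies the prediction framework: the pairing state of the G,G,A bases is
#' decisive first (fully or partially base-paired motifs), then the hairpin
#' geometry of unpaired motifs. A canonical high-affinity element is the
#' hexanucleotide loop A-N-GGA-X sitting directly on a stem of at least two
#' stacked pairs; pentaloops lacking N (AGGAX) or carrying a purine N with no
#' X (ARGGA), loops with nucleotides inserted between the element and the
#' stem, and stem-less single-stranded motifs are progressively weaker or
#' differently ranked contexts.
#'
#' @param rna An [rna_molecule()].
#' @param gga_start 0-based start position of a GGA occurrence.
#' @return An object of class `gga_motif`: list with `rna_name`, `gga_start`
#'   (0-based), `gga_span` (1-based inclusive, for reports), `context`,
#'   `anchor_A` (0-based position or `NA`), `n_nucleotide`, `x_nucleotide`,
#'   `closing_pair`, `closing_pair_is_CG`, `penultimate_pair`, `stem_length`,
#'   `inserted_count`, `n_paired`, `loop_len`, `flags` (character vector) and
#'   `tier` (filled by [assign_tier()]).
#' @export
classify_context <- function(rna, gga_start) {
  stopifnot(inherits(rna, "rna_molecule"))
  g1 <- gga_start
  if (substr(rna$sequence, g1 + 1L, g1 + 3L) != "GGA") {
    stop("no GGA at 0-based position ", g1, " of ", sQuote(rna$name), call. = FALSE)
  }
  ps <- pairing_status(rna, g1, g1 + 3L)
  # upstream anchor adenine: A directly 5' of the GGA (AGGA) or one base
  # further with an intervening N (ANGGA); ANGGA register preferred when both
  # are A (the looped-out N is then read as A)
  anchor <- NA_integer_; n_base <- NA_character_
  if (identical(base_at(rna, g1 - 2L), "A")) {
    anchor <- g1 - 2L
    n_base <- base_at(rna, g1 - 1L)
  } else if (identical(base_at(rna, g1 - 1L), "A")) {
    anchor <- g1 - 1L
  }
  x_base <- base_at(rna, g1 + 3L)

  motif <- list(
    rna_name = rna$name,
    gga_start = g1,
    gga_span = c(g1 + 1L, g1 + 3L),
    context = NA_character_,
    anchor_A = anchor,
    n_nucleotide = n_base,
    x_nucleotide = x_base,
    closing_pair = NA_character_,
    closing_pair_is_CG = NA,
    penultimate_pair = NA_character_,
    stem_length = 0L,
    inserted_count = NA_integer_,
    n_paired = unname(ps["n_paired"]),
    loop_len = NA_integer_,
    flags = character(0),
    tier = NA_character_
  )

  if (ps["n_paired"] == 3L) {
    motif$context <- "FULLY_PAIRED"
    return(structure(motif, class = "gga_motif"))
  }
  if (ps["n_paired"] >= 1L) {
    motif$context <- "PARTIALLY_PAIRED"
    return(structure(motif, class = "gga_motif"))
  }

  ctx <- hairpin_context(rna, g1)
  if (ctx$kind == "hairpin" && ctx$stem_length >= 2L) {
    loop <- substr(rna$sequence, ctx$loop_start + 1L, ctx$loop_end)
    loop_len <- nchar(loop)
    motif$loop_len <- loop_len
    motif$closing_pair <- ctx$closing_pair
    motif$closing_pair_is_CG <- identical(ctx$closing_pair, "C-G")
    motif$penultimate_pair <- ctx$penultimate_pair
    motif$stem_length <- ctx$stem_length
    off <- g1 - ctx$loop_start  # motif offset within the loop
    if (loop_len == 6L && off == 2L && substr(loop, 1, 1) == "A") {
      # loop reads A N G G A X exactly
      motif$context <- "HEXALOOP_ON_STEM"
      motif$anchor_A <- ctx$loop_start
      motif$n_nucleotide <- substr(loop, 2, 2)
      motif$x_nucleotide <- substr(loop, 6, 6)
      motif$inserted_count <- 0L
    } else if (loop_len == 5L && off == 2L && substr(loop, 1, 1) == "A" &&
               substr(loop, 2, 2) %in% c("A", "G")) {
      # A R G G A, purine R, no X
      motif$context <- "PURINE_PENTALOOP"
      motif$anchor_A <- ctx$loop_start
      motif$n_nucleotide <- substr(loop, 2, 2)
      motif$x_nucleotide <- NA_character_
      motif$inserted_count <- 0L
    } else if (loop_len == 5L && off == 1L && substr(loop, 1, 1) == "A") {
      # A G G A X, N missing
      motif$context <- "PENTALOOP_NO_N"
      motif$anchor_A <- ctx$loop_start
      motif$n_nucleotide <- NA_character_
      motif$x_nucleotide <- substr(loop, 5, 5)
      motif$inserted_count <- 0L
    } else {
      motif$context <- "EXPANDED_LOOP"
      elem_len <- if (!is.na(motif$anchor_A)) (g1 + 4L) - motif$anchor_A else 4L
      motif$inserted_count <- max(0L, loop_len - elem_len)
      if (motif$inserted_count == 0L) motif$inserted_count <- max(1L, loop_len - 6L)
      if (motif$inserted_count > 4L) {
        motif$flags <- c(motif$flags, "insertion_count_extrapolated")
      }
    }
    return(structure(motif, class = "gga_motif"))
  }

  # unpaired but not on an adequate stem: single-stranded context
  motif$context <- "SINGLE_STRANDED"
  if (ctx$kind == "hairpin") motif$flags <- c(motif$flags, "loop_on_single_pair_stem")
  if (ctx$kind == "single_stranded" && ctx$loop_start > 0L &&
      ctx$loop_end < rna$length) {
    motif$flags <- c(motif$flags, "internal_loop_or_bulge")
  }
  if (is.na(motif$n_nucleotide)) {
    # 2'-OH/backbone contacts substitute for the looped-out nucleotide, so a
    # missing N in a single-stranded motif barely changes affinity
    motif$flags <- c(motif$flags, "n_absent_ss_backbone_compensated")
  }
  structure(motif, class = "gga_motif")
}

#' Assign an affinity tier to a classified motif
#'
#' Hexaloops on stems and purine pentaloops are high affinity; pentaloops
#' without N, expanded loops and single-stranded motifs are intermediate;
#' partially base-paired motifs are low and fully paired motifs very low. An
#' unpaired motif lacking the upstream anchor adenine is demoted by one tier
#' (paired contexts already price the burial, so no anchor demotion there);
#' expanded
#' loops with more than four inserted nucleotides drop to intermediate-low
#' (an extrapolation beyond the measured constructs, flagged as such).
#'
#' @param motif A `gga_motif` from [classify_context()].
#' @return The motif with `tier`, `kd_lower`, `kd_upper` filled.
#' @export
assign_tier <- function(motif) {
  stopifnot(inherits(motif, "gga_motif"))
  tier <- switch(motif$context,
    HEXALOOP_ON_STEM = "HIGH",
    PURINE_PENTALOOP = "HIGH",
    PENTALOOP_NO_N   = "INTERMEDIATE",
    EXPANDED_LOOP    = "INTERMEDIATE",
    SINGLE_STRANDED  = "INTERMEDIATE",
    PARTIALLY_PAIRED = "LOW",
    FULLY_PAIRED     = "VERY_LOW",
    stop("unclassified motif", call. = FALSE)
  )
  if (identical(motif$context, "EXPANDED_LOOP") &&
      !is.na(motif$inserted_count) && motif$inserted_count > 4L) {
    tier <- "INTERMEDIATE_LOW"
  }
  unpaired_ctx <- !motif$context %in% c("PARTIALLY_PAIRED", "FULLY_PAIRED")
  if (is.na(motif$anchor_A) && unpaired_ctx) {
    i <- match(tier, TIER_LEVELS)
    tier <- TIER_LEVELS[min(i + 1L, length(TIER_LEVELS))]
    motif$flags <- unique(c(motif$flags, "anchor_A_absent_demoted"))
  }
  b <- tier_bounds(tier)
  motif$tier <- tier
  motif$kd_lower <- b$kd_lower
  motif$kd_upper <- b$kd_upper
  motif
}

#' @export
print.gga_motif <- function(x, ...) {
  cat("<gga_motif> ", x$rna_name, " GGA_", x$gga_span[1], "-", x$gga_span[2],
      "  context=", x$context,
      if (!is.na(x$tier)) paste0("  tier=", x$tier) else "", "\n", sep = "")
  invisible(x)
}

# choose one representative per group of mutually overlapping raw GGA hits:
# prefer canonical loop registers, then motifs with the anchor A, then leftmost
dedupe_motifs <- function(motifs) {
  if (length(motifs) <= 1L) return(motifs)
  starts <- vapply(motifs, function(m) m$gga_start, integer(1))
  grp <- cumsum(c(1L, diff(starts) >= 3L))
  keep <- lapply(split(seq_along(motifs), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    ms <- motifs[idx]
    canonical <- vapply(ms, function(m)
      m$context %in% c("HEXALOOP_ON_STEM", "PURINE_PENTALOOP", "PENTALOOP_NO_N"),
      logical(1))
    anchored <- vapply(ms, function(m) !is.na(m$anchor_A), logical(1))
    ord <- order(!canonical, !anchored, vapply(ms, function(m) m$gga_start, integer(1)))
    idx[ord[1]]
  })
  motifs[sort(unlist(keep, use.names = FALSE))]
}

#' Scan a molecule for GGA motifs and predict their affinity tiers
#'
#' @param rna An [rna_molecule()].
#' @return Object of class `motif_report`: list with `rna_name`, `motifs`
#'   (list of tier-assigned `gga_motif`, ordered by position, overlapping
#'   raw hits deduplicated by the anchor rule), `raw_count` (all overlapping
#'   GGA windows) and `tier_counts` (named integer vector over tiers).
#' @examples
#' m <- rna_molecule("sl2-like", "GGCUACGGAUAGCC", "((((......))))")
#' scan_motifs(m)
#' @export
scan_motifs <- function(rna) {
  stopifnot(inherits(rna, "rna_molecule"))
  hits <- find_gga(rna)
  motifs <- lapply(hits, function(h) assign_tier(classify_context(rna, h)))
  motifs <- dedupe_motifs(motifs)
  tiers <- vapply(motifs, function(m) m$tier, character(1))
  counts <- table(factor(tiers, levels = TIER_LEVELS))
  structure(
    list(rna_name = rna$name, motifs = motifs, raw_count = length(hits),
         tier_counts = as.integer(counts) |> stats::setNames(TIER_LEVELS)),
    class = "motif_report"
  )
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report> ", x$rna_name, ": ", length(x$motifs), " motif(s)\n", sep = "")
  for (m in x$motifs) print(m)
  nz <- x$tier_counts[x$tier_counts > 0]
  if (length(nz)) cat("tiers:", paste(names(nz), nz, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Motif report as a data frame
#'
#' One row per motif with 1-based inclusive coordinates, suitable for TSV
#' export.
#'
#' @param report A `motif_report` (or list of them).
#' @return Data frame with columns `name`, `start`, `end`, `context`, `tier`,
#'   `kd_lower`, `kd_upper`, `anchor_A`, `n_nucleotide`, `x_nucleotide`,
#'   `closing_pair`, `penultimate_pair`, `stem_length`, `inserted_count`,
#'   `n_paired`, `flags`.
#' @export
motif_report_table <- function(report) {
  reports <- if (inherits(report, "motif_report")) list(report) else report
  rows <- lapply(reports, function(rep) {
    if (length(rep$motifs) == 0L) return(NULL)
    do.call(rbind, lapply(rep$motifs, function(m) {
      data.frame(
        name = rep$rna_name, start = m$gga_span[1], end = m$gga_span[2],
        context = m$context, tier = m$tier,
        kd_lower = m$kd_lower, kd_upper = m$kd_upper,
        anchor_A = if (is.na(m$anchor_A)) NA_integer_ else m$anchor_A + 1L,
        n_nucleotide = m$n_nucleotide, x_nucleotide = m$x_nucleotide,
        closing_pair = m$closing_pair, penultimate_pair = m$penultimate_pair,
        stem_length = m$stem_length, inserted_count = m$inserted_count,
        n_paired = m$n_paired,
        flags = paste(m$flags, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), start = integer(0), end = integer(0),
                      context = character(0), tier = character(0),
                      kd_lower = numeric(0), kd_upper = numeric(0),
                      anchor_A = integer(0), n_nucleotide = character(0),
                      x_nucleotide = character(0), closing_pair = character(0),
                      penultimate_pair = character(0), stem_length = integer(0),
                      inserted_count = integer(0), n_paired = integer(0),
                      flags = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Measured reference affinities packaged with the framework
#'
#' Dissociation constants of the benchmark RsmE-binding RNAs: the RsmZ
#' stem-loops SL1-SL4 and the single-stranded region between SL2 and SL3, the
#' ribosome-binding-site hairpin of the hcnA mRNA, and the five GGA motifs of
#' the hcnA 5'-UTR. Two-site entries carry the macroscopic constants of the
#' first and second binding event to the protein homodimer; entries for which
#' only a range or a tier is established carry that range/tier.
#'
#' @return Data frame with columns `rna_name`, `context`, `tier`, `kd1`,
#'   `kd2` (molar, `NA` when not applicable), `kd_min`, `kd_max` (molar range
#'   when only a range is established), `model` (`"two_site"`, `"one_site"`,
#'   `"nmr"`, `"tier_only"`) and `source`.
#' @export
reference_table <- function() {
  df <- data.frame(
    rna_name = c("SL2", "20nt-RBS", "SL1", "SL3", "SL4", "9nt-GGA_39-41",
                 "hcnA-GGA#1", "hcnA-GGA#2",
                 "hcnA-GGA#3", "hcnA-GGA#4", "hcnA-GGA#5"),
    context = c("HEXALOOP_ON_STEM", "HEXALOOP_ON_STEM", "EXPANDED_LOOP",
                "PENTALOOP_NO_N", "PENTALOOP_NO_N", "SINGLE_STRANDED",
                "PARTIALLY_PAIRED", "FULLY_PAIRED",
                NA, NA, NA),
    tier = c("HIGH", "HIGH", "INTERMEDIATE", "INTERMEDIATE", "INTERMEDIATE",
             "INTERMEDIATE", "LOW", "VERY_LOW",
             "INTERMEDIATE", "INTERMEDIATE_LOW", "HIGH"),
    kd1 = c(16e-9, 10e-9, NA, NA, NA, NA, 300e-6, 2.7e-3, NA, NA, NA),
    kd2 = c(185e-9, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    kd_min = c(NA, NA, 1.5e-6, 1.5e-6, 1.5e-6, 1.5e-6, NA, NA, NA, NA, NA),
    kd_max = c(NA, NA, 3.5e-6, 3.5e-6, 3.5e-6, 3.5e-6, NA, NA, NA, NA, NA),
    model = c("two_site", "two_site", "one_site", "one_site", "one_site",
              "one_site", "nmr", "nmr", "tier_only", "tier_only", "tier_only"),
    source = c("ITC, two-site fit", "ITC, two-site fit; ~10 nM scale",
               "ITC, 1.5-3.5 uM range", "ITC, 1.5-3.5 uM range",
               "ITC, 1.5-3.5 uM range", "ITC, 1.5-3.5 uM range",
               "NMR peak integrals at 0.54 mM totals",
               "NMR peak integrals at 0.54 mM totals",
               "predicted intermediate, ITC-verified",
               "predicted intermediate-low, ITC-verified",
               "predicted high, ITC-verified"),
    stringsAsFactors = FALSE
  )
  df
}

#' Span of the reference affinities in log10 units
#'
#' @return `log10(max Kd / min Kd)` over every numeric dissociation constant
#'   in [reference_table()].
#' @export
reference_affinity_span <- function() {
  rt <- reference_table()
  kds <- c(rt$kd1, rt$kd2, rt$kd_min, rt$kd_max)
  kds <- kds[!is.na(kds)]
  log10(max(kds) / min(kds))
}
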