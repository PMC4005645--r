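# shared fixtures and independent oracles used across test files

all_context_classes <- c("HEXALOOP_ON_STEM", "PURINE_PENTALOOP",
                         "PENTALOOP_NO_N", "EXPANDED_LOOP", "SINGLE_STRANDED",
                         "PARTIALLY_PAIRED", "FULLY_PAIRED")

# generator arguments that vary the planted geometry with the seed
planted_spec_args <- function(cls, seed) {
  set.seed(seed + 7919L)
  args <- list(context = cls, seed = seed,
               stem_length = sample(2:6, 1),
               flank = sample(0:4, 1))
  if (cls == "PURINE_PENTALOOP") {
    args$n_base <- sample(c("A", "G"), 1)
  } else {
    args$n_base <- sample(c("A", "C", "G", "U"), 1)
  }
  args$x_base <- sample(c("A", "C", "G", "U"), 1)
  if (cls == "EXPANDED_LOOP") args$inserted <- sample(1:4, 1)
  if (cls == "PARTIALLY_PAIRED") args$n_buried <- sample(1:2, 1)
  if (cls == "FULLY_PAIRED") args$stem_length <- sample(5:8, 1)
  if (cls == "SINGLE_STRANDED" && runif(1) < 0.5) args$n_base <- NA
  args
}

# brute-force window enumeration: independent oracle for find_gga
oracle_gga_windows <- function(sequence) {
  n <- nchar(sequence)
  if (n < 3) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - 2)) {
    if (substr(sequence, i, i + 2) == "GGA") starts <- c(starts, i - 1L)
  }
  starts
}

# independent bound-fraction oracle: bisection on the mass balance
oracle_bound_fraction <- function(kd, p_tot, r_tot) {
  g <- function(cc) kd * cc - (p_tot - cc) * (r_tot - cc)
  lo <- 0; hi <- min(p_tot, r_tot)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  ((lo + hi) / 2) / min(p_tot, r_tot)
}

# independent free-ligand oracle for the two-site model: plain bisection on
# the monotone site balance, no shared code with free_ligand()
oracle_free_ligand_two_site <- function(l_tot, p_tot, kd1, kd2) {
  g <- function(l) {
    z <- 1 + l / kd1 + l^2 / (kd1 * kd2)
    pf <- p_tot / z
    l + pf * l / kd1 + 2 * pf * l^2 / (kd1 * kd2) - l_tot
  }
  lo <- 0; hi <- l_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# fixed-point iteration oracle for the multi-pool free-site concentration
oracle_free_sites_fixed_point <- function(m, kd, site_total, iters = 20000) {
  s <- site_total / 2
  for (i in seq_len(iters)) {
    s_new <- site_total / (1 + sum(m / (kd + s)))
    if (abs(s_new - s) < 1e-18 + 1e-15 * site_total) { s <- s_new; break }
    s <- s_new
  }
  s
}
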