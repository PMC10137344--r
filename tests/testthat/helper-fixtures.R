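# Small in-code fixtures shared across the suite.

# A flat-frequency toy genome.
tiny_genome <- function(n_chr = 2, len = 1, m = 50, freq = 0.5, seed = 1) {
  make_genome(n_chr, len, m, freq_sampler = function(n) rep(freq, n),
              seed = seed)
}

# Build a population directly from haplotype matrices.
make_pop <- function(hap1, hap2, sex = NULL, gen = "test",
                     ids = paste0("ind", seq_len(nrow(hap1)))) {
  n <- nrow(hap1)
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  kisim:::new_population(ids, sex, rep(gen, n), rep(NA_character_, n),
                         rep(NA_character_, n), hap1, hap2)
}

# A hand-made purely additive architecture (scale 1 unless given).
make_arch <- function(qtl, a, d = rep(0, length(a)),
                      epi = matrix(numeric(0), ncol = 3,
                                   dimnames = list(NULL, c("qtl1", "qtl2",
                                                           "effect"))),
                      scale = 1, trait_id = "t1") {
  structure(list(trait_id = trait_id, qtl_indices = as.integer(qtl),
                 additive = a, dominance = d, epistasis = epi,
                 scale = scale),
            class = "trait_architecture")
}

# A small but complete breeding configuration for program-level tests.
tiny_config <- function(...) {
  breeding_config(founder_n = 40, n_sires = 2, n_dams = 5,
                  historical_generations = 3, reproduction_generations = 2,
                  qtl_counts = c(5, 10), n_chromosomes = 2,
                  markers_per_chromosome = 50, seed = 1, ...)
}

# Independent per-locus loop oracle for the KIS score.
kis_oracle <- function(Z, ideal) {
  out <- numeric(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    s <- 0
    for (r in seq_len(nrow(ideal))) {
      z <- Z[i, ideal$locus[r]]
      b <- if (ideal$allele[r] == 1) z else 2 - z
      s <- s + ideal$weight[r] * b
    }
    out[i] <- s
  }
  out
}
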