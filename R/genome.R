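#' Build a genome map
#'
#' Defines the marker scaffold of the simulation: `n_chromosomes` autosomes
#' of equal genetic length carrying `markers_per_chromosome` equally spaced
#' markers each.  Founder allele frequencies (of the "1" allele) are drawn
#' independently per marker from `freq_sampler`.
#'
#' @param n_chromosomes Number of autosomes (default 10).
#' @param chromosome_length Genetic length of each chromosome in Morgans
#'   (default 1).
#' @param markers_per_chromosome Markers per chromosome (default 500).
#' @param freq_sampler Function of one argument `n` returning `n` founder
#'   allele frequencies in `[0, 1]`; default `Uniform(0.05, 0.95)`.
#' @param seed Integer seed for the frequency draw.
#' @return A `genome_map` object: list with `n_chromosomes`,
#'   `markers_per_chromosome`, `chromosome_length`, `positions` (Morgans,
#'   within-chromosome), `chromosome` (index per marker), `n_markers` and
#'   `founder_freqs`.
#' @export
#' @examples
#' g <- make_genome(2, 1, 10, seed = 1)
#' g$n_markers
make_genome <- function(n_chromosomes = 10L,
                        chromosome_length = 1,
                        markers_per_chromosome = 500L,
                        freq_sampler = function(n) runif(n, 0.05, 0.95),
                        seed = 1L) {
  if (n_chromosomes < 1 || markers_per_chromosome < 1)
    stop_config("n_chromosomes and markers_per_chromosome must be >= 1")
  if (chromosome_length < 0) stop_config("chromosome_length must be >= 0")
  m <- as.integer(markers_per_chromosome)
  pos1 <- if (m == 1L) 0 else seq(0, chromosome_length, length.out = m)
  set.seed(seed)
  freqs <- freq_sampler(n_chromosomes * m)
  if (any(freqs < 0 | freqs > 1)) stop_config("frequencies must lie in [0,1]")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = m,
    chromosome_length = chromosome_length,
    positions = rep(pos1, n_chromosomes),
    chromosome = rep(seq_len(n_chromosomes), each = m),
    n_markers = as.integer(n_chromosomes * m),
    founder_freqs = freqs
  ), class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", x$n_chromosomes, "chromosomes x",
      x$markers_per_chromosome, "markers,",
      x$chromosome_length, "Morgans each\n")
  invisible(x)
}

new_population <- function(id, sex, gen, sire, dam, hap1, hap2) {
  stopifnot(length(id) == nrow(hap1), all(dim(hap1) == dim(hap2)))
  structure(list(id = as.character(id), sex = sex, generation = gen,
                 sire = as.character(sire), dam = as.character(dam),
                 hap1 = hap1, hap2 = hap2),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("population:", n_individuals(x), "individuals (",
      sum(x$sex == "M"), "M /", sum(x$sex == "F"), "F ),",
      ncol(x$hap1), "markers, generation",
      paste(unique(x$generation), collapse = ","), "\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `population`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) nrow(pop$hap1)

#' Genotype dosage matrix of a population
#'
#' @param pop A `population`.
#' @return Integer matrix (individuals x markers) of 0/1/2 counts of the
#'   "1" allele, with individual ids as row names.
#' @export
genotypes <- function(pop) {
  Z <- pop$hap1 + pop$hap2
  rownames(Z) <- pop$id
  Z
}

#' Subset a population by index or id
#' @param pop A `population`.
#' @param i Integer indices or character ids.
#' @return A `population` with the selected individuals.
#' @export
subset_population <- function(pop, i) {
  if (is.character(i)) i <- match(i, pop$id)
  new_population(pop$id[i], pop$sex[i], pop$generation[i],
                 pop$sire[i], pop$dam[i],
                 pop$hap1[i, , drop = FALSE], pop$hap2[i, , drop = FALSE])
}

combine_populations <- function(...) {
  ps <- list(...)
  new_population(unlist(lapply(ps, `[[`, "id")),
                 unlist(lapply(ps, `[[`, "sex")),
                 unlist(lapply(ps, `[[`, "generation")),
                 unlist(lapply(ps, `[[`, "sire")),
                 unlist(lapply(ps, `[[`, "dam")),
                 do.call(rbind, lapply(ps, `[[`, "hap1")),
                 do.call(rbind, lapply(ps, `[[`, "hap2")))
}

#' Simulate a founder population in linkage equilibrium
#'
#' Each haplotype allele is an independent Bernoulli draw at the marker's
#' founder frequency; sexes are exactly half male, half female.
#'
#' @param genome A [make_genome()] map.
#' @param n Even number of founders.
#' @param seed Integer seed.
#' @param generation Generation label (default `"hist0"`).
#' @param id_prefix Prefix for individual ids.
#' @return A `population`.
#' @export
simulate_founders <- function(genome, n, seed = 1L, generation = "hist0",
                              id_prefix = "F") {
  if (n %% 2 != 0 || n < 2) stop_config("founder count must be even and >= 2")
  set.seed(seed)
  M <- genome$n_markers
  p <- rep(genome$founder_freqs, each = n)
  hap1 <- matrix(rbinom(n * M, 1L, p), nrow = n)
  hap2 <- matrix(rbinom(n * M, 1L, p), nrow = n)
  sex <- sample(rep(c("M", "F"), n / 2))
  new_population(paste0(id_prefix, seq_len(n)), sex,
                 rep(generation, n), rep(NA_character_, n),
                 rep(NA_character_, n), hap1, hap2)
}

#' Simulate one gamete from a parent
#'
#' Crossovers per chromosome are Poisson(chromosome length in Morgans) with
#' uniform positions and no interference (Haldane model); the starting
#' strand is chosen with probability 1/2; there is no mutation.
#'
#' @param hap1,hap2 The parent's two haplotypes (0/1 vectors over all
#'   markers).
#' @param genome The genome map.
#' @param seed Optional integer seed.
#' @return Integer 0/1 gamete haplotype.
#' @export
meiosis <- function(hap1, hap2, genome, seed = NULL) {
  if (length(hap1) != genome$n_markers || length(hap2) != genome$n_markers)
    stop("haplotype length does not match genome")
  if (!is.null(seed)) set.seed(seed)
  g <- cpp_make_gametes(matrix(as.integer(hap1), nrow = 1),
                        matrix(as.integer(hap2), nrow = 1),
                        0L,
                        as.integer((seq_len(genome$n_chromosomes) - 1L) *
                                     genome$markers_per_chromosome),
                        rep(genome$markers_per_chromosome,
                            genome$n_chromosomes),
                        rep(genome$chromosome_length, genome$n_chromosomes),
                        genome$positions)
  drop(g)
}

# Internal: many gametes at once. parent_idx is 1-based into pop.
make_gametes <- function(pop, parent_idx, genome) {
  cpp_make_gametes(pop$hap1, pop$hap2, as.integer(parent_idx - 1L),
                   as.integer((seq_len(genome$n_chromosomes) - 1L) *
                                genome$markers_per_chromosome),
                   rep(genome$markers_per_chromosome, genome$n_chromosomes),
                   rep(genome$chromosome_length, genome$n_chromosomes),
                   genome$positions)
}

#' Produce offspring from selected sires and dams
#'
#' Dams are allocated to sires and offspring to dams as evenly as possible
#' (exactly evenly whenever the counts divide); each offspring receives one
#' recombinant gamete from its sire and one from its dam; offspring sexes
#' are exactly half male, half female.
#'
#' @param sires,dams `population`s of the selected parents.
#' @param n_offspring Even number of offspring.
#' @param genome The genome map.
#' @param generation_label Label recorded for the offspring.
#' @param seed Integer seed.
#' @param id_prefix Prefix for offspring ids (default the generation label).
#' @return A `population` with pedigree (`sire`, `dam`) filled in.
#' @export
produce_offspring <- function(sires, dams, n_offspring, genome,
                              generation_label, seed = 1L,
                              id_prefix = generation_label) {
  ns <- n_individuals(sires); nd <- n_individuals(dams)
  if (ns < 1 || nd < 1) stop_config("need at least one sire and one dam")
  if (n_offspring < 2 || n_offspring %% 2 != 0)
    stop_config("n_offspring must be even and >= 2")
  set.seed(seed)
  # dams per sire, as even as possible
  sire_of_dam <- sample(rep(seq_len(ns), length.out = nd))
  # offspring per dam, as even as possible
  k <- n_offspring %/% nd
  extra <- n_offspring - k * nd
  per_dam <- rep(k, nd)
  if (extra > 0) per_dam[sample.int(nd, extra)] <- k + 1L
  dam_idx <- rep(seq_len(nd), per_dam)
  sire_idx <- sire_of_dam[dam_idx]
  hap1 <- make_gametes(sires, sire_idx, genome)  # paternal haplotype
  hap2 <- make_gametes(dams, dam_idx, genome)    # maternal haplotype
  sex <- sample(rep(c("M", "F"), n_offspring / 2))
  new_population(paste0(id_prefix, "_", seq_len(n_offspring)), sex,
                 rep(generation_label, n_offspring),
                 sires$id[sire_idx], dams$id[dam_idx], hap1, hap2)
}
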