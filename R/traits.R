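#' Assign a trait architecture calibrated to unit genetic variance
#'
#' Samples `n_qtl` QTL positions without replacement (avoiding
#' `exclude_indices`, so that two traits can be given disjoint QTL sets),
#' draws raw additive effects from `effect_sampler`, and sets the
#' calibration `scale` so that the sample variance of the true breeding
#' value over the supplied founder population is exactly 1.
#'
#' @param genome A [make_genome()] map.
#' @param n_qtl Number of additive QTLs.
#' @param founders The founder `population` used for variance calibration.
#' @param effect_sampler Function of `n` returning raw additive effects;
#'   default standard normal.
#' @param exclude_indices Marker indices that may not become QTLs.
#' @param seed Integer seed.
#' @param trait_id Trait label.
#' @return A `trait_architecture`: list with `trait_id`, `qtl_indices`,
#'   `additive` (raw effects), `dominance`, `epistasis` (3-column matrix:
#'   two QTL indices and a raw effect), and `scale`.
#' @export
assign_trait <- function(genome, n_qtl, founders,
                         effect_sampler = rnorm,
                         exclude_indices = integer(0),
                         seed = 1L, trait_id = "trait1") {
  avail <- setdiff(seq_len(genome$n_markers), exclude_indices)
  if (n_qtl > length(avail))
    stop_config("n_qtl exceeds the number of available markers")
  set.seed(seed)
  qtl <- sort(sample(avail, n_qtl))
  a <- effect_sampler(n_qtl)
  arch <- structure(list(trait_id = trait_id,
                         qtl_indices = qtl,
                         additive = a,
                         dominance = rep(0, n_qtl),
                         epistasis = matrix(numeric(0), ncol = 3,
                                            dimnames = list(NULL,
                                              c("qtl1", "qtl2", "effect"))),
                         scale = 1),
                    class = "trait_architecture")
  calibrate_architecture(arch, founders)
}

# Rescale so that the founder sample variance of the total genetic value is
# exactly 1 (TBV when the architecture is purely additive).
calibrate_architecture <- function(arch, founders) {
  arch$scale <- 1
  g <- genotypic_value(genotypes(founders), arch)
  s <- stats::sd(g)
  if (!is.finite(s) || s == 0)
    stop("calibration failed: founder genetic variance is zero ",
         "(all QTLs monomorphic?)")
  arch$scale <- 1 / s
  arch
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("trait_architecture", x$trait_id, ":", length(x$qtl_indices),
      "QTLs,", sum(x$dominance != 0), "with dominance,",
      nrow(x$epistasis), "epistatic pairs, scale", signif(x$scale, 4), "\n")
  invisible(x)
}

#' Add dominance and/or epistatic effects to an architecture
#'
#' `round(proportion * nQTL)` QTLs gain dominance effects and/or
#' `round(proportion * nQTL)` disjoint additive-by-additive pairs are
#' created among randomly chosen QTLs; raw non-additive effects come from
#' `effect_sampler` and the total genetic-value variance is recalibrated to
#' 1 on the founders.
#'
#' @param arch A `trait_architecture`.
#' @param proportion Fraction of the QTL count, in `[0, 1]` (0 is a no-op).
#' @param mode One of `"dominance"`, `"epistasis"`, `"both"`.
#' @param founders Founder `population` for recalibration.
#' @param effect_sampler Raw effect sampler (default standard normal).
#' @param seed Integer seed.
#' @return The modified `trait_architecture`.
#' @export
add_nonadditive <- function(arch, proportion, mode = c("dominance",
                                                       "epistasis", "both"),
                            founders, effect_sampler = rnorm, seed = 1L) {
  mode <- match.arg(mode)
  if (proportion < 0 || proportion > 1)
    stop_config("proportion must lie in [0, 1]")
  if (proportion == 0) return(arch)
  n_qtl <- length(arch$qtl_indices)
  k <- round(proportion * n_qtl)
  if (k == 0) return(arch)
  set.seed(seed)
  if (mode %in% c("dominance", "both")) {
    pick <- sample.int(n_qtl, k)
    d <- rep(0, n_qtl)
    d[pick] <- effect_sampler(k)
    arch$dominance <- d
  }
  if (mode %in% c("epistasis", "both")) {
    if (2L * k > n_qtl)
      stop_config("not enough QTLs for ", k, " disjoint epistatic pairs")
    members <- sample(arch$qtl_indices, 2L * k)
    arch$epistasis <- cbind(qtl1 = members[seq_len(k)],
                            qtl2 = members[k + seq_len(k)],
                            effect = effect_sampler(k))
  }
  calibrate_architecture(arch, founders)
}

#' True breeding value
#'
#' The additive merit `TBV_i = sum_j Z_ij * a_j * scale` over the QTLs of
#' one trait; for a list of architectures the per-trait TBVs are summed
#' (the combined two-trait objective used from the cross onward).
#'
#' @param Z Dosage matrix (individuals x markers, 0/1/2) covering all QTL
#'   columns, or a `population`.
#' @param arch A `trait_architecture` or list of them.
#' @return Numeric TBV per individual.
#' @export
true_breeding_value <- function(Z, arch) {
  if (inherits(Z, "population")) Z <- genotypes(Z)
  if (inherits(arch, "trait_architecture")) arch <- list(arch)
  out <- numeric(nrow(Z))
  for (a in arch) {
    if (max(a$qtl_indices) > ncol(Z))
      stop("genotype matrix does not cover all QTL columns")
    out <- out + drop(Z[, a$qtl_indices, drop = FALSE] %*%
                        (a$additive * a$scale))
  }
  out
}

#' Total genotypic value including dominance and epistasis
#'
#' Additive part plus `d_j` for each heterozygous QTL plus
#' `e_jk * w_j * w_k` for each epistatic pair, where `w = Z - 1` is the
#' centered dosage; all terms share the trait's calibration scale.  Equals
#' [true_breeding_value()] when all non-additive effects are zero.
#'
#' @inheritParams true_breeding_value
#' @param het Optional logical/0-1 heterozygosity matrix matching `Z`
#'   (derived from a `population`'s haplotypes when `Z` is a population,
#'   otherwise `Z == 1`).
#' @return Numeric genotypic value per individual.
#' @export
genotypic_value <- function(Z, arch, het = NULL) {
  if (inherits(Z, "population")) {
    het <- Z$hap1 != Z$hap2
    Z <- genotypes(Z)
  }
  if (is.null(het)) het <- Z == 1L
  if (inherits(arch, "trait_architecture")) arch <- list(arch)
  out <- numeric(nrow(Z))
  for (a in arch) {
    if (max(a$qtl_indices) > ncol(Z))
      stop("genotype matrix does not cover all QTL columns")
    g <- drop(Z[, a$qtl_indices, drop = FALSE] %*% a$additive)
    if (any(a$dominance != 0))
      g <- g + drop(het[, a$qtl_indices, drop = FALSE] %*% a$dominance)
    if (nrow(a$epistasis) > 0) {
      W <- Z - 1
      for (r in seq_len(nrow(a$epistasis)))
        g <- g + a$epistasis[r, "effect"] *
          W[, a$epistasis[r, "qtl1"]] * W[, a$epistasis[r, "qtl2"]]
    }
    out <- out + g * a$scale
  }
  out
}

#' Generate phenotypes at a given heritability
#'
#' `y = g + e` with `e ~ N(0, Var(g) * (1 - h2) / h2)`, where `Var(g)` is
#' the sample variance of the supplied genetic values; `h2 = 1` returns the
#' genetic values unchanged.
#'
#' @param genetic_values Numeric vector of genetic values.
#' @param h2 Heritability in `(0, 1]`.
#' @param seed Integer seed.
#' @return Numeric phenotypes.
#' @export
phenotype <- function(genetic_values, h2, seed = 1L) {
  if (h2 <= 0 || h2 > 1) stop_config("h2 must lie in (0, 1]")
  n <- length(genetic_values)
  vg <- if (n > 1) stats::var(genetic_values) else 0
  ve <- vg * (1 - h2) / h2
  set.seed(seed)
  genetic_values + rnorm(n, 0, sqrt(ve))
}
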