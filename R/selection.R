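new_ideal <- function(locus, allele, weight, subsystem) {
  if (anyDuplicated(locus)) stop("ideal loci must be distinct")
  if (any(weight < 0)) stop("ideal weights must be >= 0")
  structure(data.frame(locus = as.integer(locus),
                       allele = as.integer(allele),
                       weight = as.numeric(weight),
                       subsystem = as.character(subsystem),
                       stringsAsFactors = FALSE),
            class = c("ideal_individual", "data.frame"))
}

#' Build an ideal individual from a trait architecture
#'
#' One locus per QTL; the beneficial allele is the one whose dosage
#' increase raises the TBV ("1" for positive additive effects, "0" for
#' negative); zero-effect loci are dropped.  Weights are 1 under equal
#' weighting or `|additive effect * scale|` under effect weighting.
#' Multiple architectures are concatenated with their trait ids as
#' subsystem labels.
#'
#' @param arch A `trait_architecture` or list of them.
#' @param weighting `"equal"` or `"effect"`.
#' @param min_effect_quantile Optional filter: drop loci whose `|effect|`
#'   falls below this quantile of the trait's `|effect|` distribution
#'   (default 0 = keep all; small-effect loci can be ignored this way).
#' @return An `ideal_individual` data frame with columns `locus`, `allele`
#'   (beneficial allele, 0/1), `weight` and `subsystem`.
#' @export
build_ideal <- function(arch, weighting = c("equal", "effect"),
                        min_effect_quantile = 0) {
  weighting <- match.arg(weighting)
  if (inherits(arch, "trait_architecture")) arch <- list(arch)
  if (length(arch) == 0) stop_config("need at least one trait architecture")
  parts <- lapply(arch, function(a) {
    if (length(a$qtl_indices) == 0) stop_config("architecture has no QTLs")
    keep <- a$additive != 0
    if (min_effect_quantile > 0) {
      thr <- stats::quantile(abs(a$additive), min_effect_quantile)
      keep <- keep & abs(a$additive) >= thr
    }
    new_ideal(a$qtl_indices[keep],
              ifelse(a$additive[keep] > 0, 1L, 0L),
              if (weighting == "effect") abs(a$additive[keep] * a$scale)
              else 1,
              a$trait_id)
  })
  out <- do.call(rbind, parts)
  if (anyDuplicated(out$locus)) stop("trait QTL sets overlap")
  class(out) <- c("ideal_individual", "data.frame")
  out
}

#' Kinship index (KIS similarity) score
#'
#' Per locus a candidate contributes `weight * b` where `b` in `{0, 1, 2}`
#' is its number of copies of the beneficial allele (0 = homozygous
#' disadvantageous, 1 = heterozygous, 2 = homozygous beneficial); the
#' kinship index KI is the sum over loci, optionally reported per
#' subsystem.
#'
#' @param Z Dosage matrix (individuals x markers) or a `population`.
#' @param ideal An `ideal_individual`.
#' @param by_subsystem If `TRUE`, return a matrix of per-subsystem scores
#'   (columns) instead of the total.
#' @return Numeric score per candidate (or a matrix when `by_subsystem`).
#' @export
kis_score <- function(Z, ideal, by_subsystem = FALSE) {
  if (inherits(Z, "population")) Z <- genotypes(Z)
  if (max(ideal$locus) > ncol(Z))
    stop("genotype matrix does not cover all ideal loci")
  ben <- Z[, ideal$locus, drop = FALSE]
  flip <- which(ideal$allele == 0L)
  if (length(flip)) ben[, flip] <- 2L - ben[, flip, drop = FALSE]
  if (!by_subsystem) return(drop(ben %*% ideal$weight))
  subs <- unique(ideal$subsystem)
  out <- sapply(subs, function(s) {
    j <- ideal$subsystem == s
    drop(ben[, j, drop = FALSE] %*% ideal$weight[j])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(Z),
                                       dimnames = list(NULL, subs))
  out
}

#' Comprehensive kinship index across trait subsystems
#'
#' The genome is divided into subsystems (one per trait or trait
#' category); each subsystem's similarity score is normalized by its
#' maximum attainable score (`2 * sum of its weights`) and the
#' comprehensive index is their importance-weighted combination.  With
#' equal importance (the default) every trait influences selection
#' equally no matter how many loci it contributes — mirroring the traits'
#' equal share of the combined breeding objective.  For a single-subsystem
#' ideal the ranking is identical to [kis_score()].
#'
#' @inheritParams kis_score
#' @param subsystem_weights Named importance weights per subsystem
#'   (default equal).
#' @return Numeric comprehensive index per candidate, in `[0, 1]` when
#'   the importance weights sum to 1.
#' @export
kis_index <- function(Z, ideal, subsystem_weights = NULL) {
  S <- kis_score(Z, ideal, by_subsystem = TRUE)
  subs <- colnames(S)
  smax <- vapply(subs, function(s)
    2 * sum(ideal$weight[ideal$subsystem == s]), 0)
  if (is.null(subsystem_weights))
    subsystem_weights <- setNames(rep(1 / length(subs), length(subs)), subs)
  if (!all(subs %in% names(subsystem_weights)))
    stop("subsystem_weights must cover every subsystem")
  w <- subsystem_weights[subs] / sum(subsystem_weights[subs])
  drop(sweep(S, 2, smax, "/") %*% w)
}

#' Nested false-negative perturbations of an ideal individual
#'
#' For each rate, `round(rate * L)` loci are deleted uniformly at random;
#' the loci missing at a lower rate are a subset of those missing at a
#' higher rate (one random deletion order is shared across rates).
#'
#' @param ideal An `ideal_individual`.
#' @param rates Ascending deletion rates, each in `[0, 1)`.
#' @param seed Integer seed.
#' @return Named list of `ideal_individual`s, one per rate.
#' @export
false_negative_ideal <- function(ideal, rates, seed = 1L) {
  if (any(rates < 0 | rates >= 1)) stop_config("rates must lie in [0, 1)")
  if (is.unsorted(rates)) stop_config("rates must be ascending")
  L <- nrow(ideal)
  set.seed(seed)
  order_out <- sample.int(L)            # shared deletion order => nesting
  out <- lapply(rates, function(r) {
    k <- round(r * L)
    kept <- if (k == 0) ideal else ideal[-order_out[seq_len(k)], ]
    class(kept) <- c("ideal_individual", "data.frame")
    kept
  })
  names(out) <- paste0("rate_", rates)
  out
}

#' Add pseudo-positive (false positive) loci to an ideal individual
#'
#' `round(rate * L)` loci are added, each the marker adjacent (index +1,
#' else -1, on the same chromosome) to a randomly chosen true locus; added
#' loci never duplicate true loci or each other, their beneficial alleles
#' are Bernoulli(1/2) and their weights are 1.
#'
#' @param ideal An `ideal_individual`.
#' @param rate Fraction of loci to add, in `[0, 1]`.
#' @param genome The genome map (for chromosome boundaries).
#' @param seed Integer seed.
#' @return An `ideal_individual` with the extra loci appended.
#' @export
false_positive_ideal <- function(ideal, rate, genome, seed = 1L) {
  if (rate < 0) stop_config("rate must be >= 0")
  k <- round(rate * nrow(ideal))
  if (k == 0) return(ideal)
  set.seed(seed)
  taken <- ideal$locus
  added <- integer(0)
  added_sub <- character(0)
  perm <- sample.int(nrow(ideal))       # random order of true loci
  ai <- 1L
  while (length(added) < k) {
    if (ai > length(perm))
      stop("cannot place pseudo-positive loci: no free adjacent markers")
    q <- ideal$locus[perm[ai]]
    sub <- ideal$subsystem[perm[ai]]
    ai <- ai + 1L
    chr <- genome$chromosome[q]
    for (cand in c(q + 1L, q - 1L)) {
      if (cand >= 1L && cand <= genome$n_markers &&
          genome$chromosome[cand] == chr &&
          !(cand %in% taken)) {
        added <- c(added, cand)
        added_sub <- c(added_sub, sub)  # pseudo locus joins its anchor's
        taken <- c(taken, cand)         # subsystem
        break
      }
    }
  }
  extra <- new_ideal(added, rbinom(k, 1L, 0.5), rep(1, k), added_sub)
  out <- rbind(ideal, extra)
  class(out) <- c("ideal_individual", "data.frame")
  out
}

#' Negative-control ideal individual
#'
#' Samples `n_loci` markers that carry no QTL effect (for any supplied
#' architecture) and assigns random beneficial alleles; selection against
#' this control should produce no genetic gain.
#'
#' @param genome The genome map.
#' @param arch A `trait_architecture` or list of them (their QTLs are
#'   excluded).
#' @param n_loci Number of control loci (default 600).
#' @param seed Integer seed.
#' @return An `ideal_individual` with unit weights.
#' @export
negative_control_ideal <- function(genome, arch, n_loci = 600L, seed = 1L) {
  if (inherits(arch, "trait_architecture")) arch <- list(arch)
  qtl <- unlist(lapply(arch, `[[`, "qtl_indices"))
  avail <- setdiff(seq_len(genome$n_markers), qtl)
  if (length(avail) < n_loci)
    stop("too few non-QTL markers for the negative control")
  set.seed(seed)
  loci <- sort(sample(avail, n_loci))
  new_ideal(loci, rbinom(n_loci, 1L, 0.5), rep(1, n_loci), "control")
}

#' Truncation selection within sex
#'
#' Selects the top `n_sires` males and top `n_dams` females by score; ties
#' are broken by a seeded random draw (not id order).
#'
#' @param scores Numeric score per candidate.
#' @param sexes `"M"`/`"F"` per candidate.
#' @param n_sires,n_dams Numbers to select.
#' @param seed Integer seed for tie-breaking.
#' @param method_tag Optional label stored on the result.
#' @return A `selection_decision`: list with `sire_idx`, `dam_idx`
#'   (indices into the candidate vector), `scores` and `method_tag`.
#' @export
select_parents <- function(scores, sexes, n_sires, n_dams, seed = 1L,
                           method_tag = "KIS") {
  males <- which(sexes == "M"); females <- which(sexes == "F")
  if (length(males) < n_sires || length(females) < n_dams)
    stop_config("not enough candidates of each sex (",
                length(males), " M / ", length(females), " F for ",
                n_sires, " sires / ", n_dams, " dams)")
  set.seed(seed)
  tb <- runif(length(scores))
  top <- function(idx, k) idx[order(-scores[idx], tb[idx])][seq_len(k)]
  structure(list(sire_idx = top(males, n_sires),
                 dam_idx = top(females, n_dams),
                 scores = scores, method_tag = method_tag),
            class = "selection_decision")
}
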