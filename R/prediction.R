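#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = W W' / (2 * sum p (1 - p))` with `W = Z - 2p`.  Monomorphic markers
#' (at the supplied reference frequencies) are excluded from both the
#' centering and the denominator.
#'
#' @param Z Dosage matrix (individuals x markers) or `population`.
#' @param freqs Reference allele frequencies per marker; default the
#'   observed column means of `Z` divided by 2.
#' @return A `grm`: list with `G` (symmetric matrix) and `reference_freqs`.
#' @export
grm_vanraden <- function(Z, freqs = NULL) {
  if (inherits(Z, "population")) Z <- genotypes(Z)
  if (is.null(freqs)) freqs <- colMeans(Z) / 2
  if (length(freqs) != ncol(Z)) stop("freqs length must match markers")
  poly <- freqs > 0 & freqs < 1
  if (!any(poly)) stop("all markers monomorphic: GRM undefined")
  p <- freqs[poly]
  W <- sweep(Z[, poly, drop = FALSE], 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  structure(list(G = tcrossprod(W) / denom, reference_freqs = freqs),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$G), "individuals, mean diagonal",
      signif(mean(diag(x$G)), 4), "\n")
  invisible(x)
}

#' GBLUP estimated breeding values
#'
#' Solves the single-trait animal model `y = 1 mu + u + e`,
#' `u ~ N(0, G sigma_u^2)`, with the variance ratio
#' `lambda = (1 - h2) / h2` treated as known and an overall mean as the
#' only fixed effect.  Candidates without phenotypes (`NA` in `y`) obtain
#' EBVs through their genomic relationships with the phenotyped set.
#'
#' @param y Phenotypes, `NA` for unphenotyped candidates; length must
#'   match `G`.
#' @param G A `grm` or a relationship matrix.
#' @param h2 Heritability in `(0, 1)`.
#' @param blend Weight of the identity blended into `G` for invertibility:
#'   `(1 - blend) G + blend I` (default 0.01; use 0 for exact SNP-BLUP
#'   equivalence).
#' @return Numeric EBV for every individual in `G`.
#' @export
gblup_ebv <- function(y, G, h2, blend = 0.01) {
  if (inherits(G, "grm")) G <- G$G
  n <- nrow(G)
  if (length(y) != n) stop("y length must match G")
  if (h2 <= 0 || h2 >= 1) stop_config("h2 must lie in (0, 1) for GBLUP")
  obs <- which(!is.na(y))
  if (length(obs) == 0) stop_config("no phenotyped individuals")
  if (blend > 0) G <- (1 - blend) * G + blend * diag(n)
  lambda <- (1 - h2) / h2
  V <- G[obs, obs, drop = FALSE] + lambda * diag(length(obs))
  Vi <- tryCatch(solve(V), error = function(e)
    stop("GBLUP system singular after regularization: ",
         conditionMessage(e)))
  yt <- y[obs]
  one <- rep(1, length(obs))
  mu <- drop(crossprod(one, Vi %*% yt) / crossprod(one, Vi %*% one))
  drop(G[, obs, drop = FALSE] %*% (Vi %*% (yt - mu)))
}

#' BayesB estimated breeding values
#'
#' Gibbs sampler over marker effects with a point mass at zero (exclusion
#' probability `pi_zero`) and marker-specific variances under a scaled
#' inverse chi-squared prior.  EBVs are `W %*% posterior mean effects`
#' for every individual (phenotyped or not), with `W` the column-centered
#' dosage matrix.
#'
#' @param y Phenotypes (`NA` for candidates without records).
#' @param Z Dosage matrix or `population` covering all individuals in `y`.
#' @param pi_zero Prior exclusion probability (default 0.95).
#' @param n_iter,n_burn Chain length and burn-in.
#' @param seed Integer seed.
#' @param df Prior degrees of freedom for marker variances (default 4.234).
#' @param scale Prior scale; default derived from `h2` and marker
#'   heterozygosity so the implied genetic variance matches `var(y) * h2`.
#' @param h2 Heritability used for the default prior scale.
#' @param fix_common_var If `TRUE`, freeze all marker variances at `scale`
#'   and the residual variance at its initial value (with `pi_zero = 0`
#'   this reproduces ridge / SNP-BLUP within MCMC error).
#' @return List with `ebv` (per individual), `effects` (posterior means),
#'   `inclusion_prob`, `mu`, and the chain settings.
#' @export
bayesb_ebv <- function(y, Z, pi_zero = 0.95, n_iter = 2000L, n_burn = 500L,
                       seed = 1L, df = 4.234, scale = NULL, h2 = 0.5,
                       fix_common_var = FALSE) {
  if (inherits(Z, "population")) Z <- genotypes(Z)
  if (pi_zero < 0 || pi_zero >= 1) stop_config("pi_zero must lie in [0, 1)")
  if (n_iter <= n_burn) stop_config("n_iter must exceed n_burn")
  if (length(y) != nrow(Z)) stop("y length must match Z rows")
  obs <- which(!is.na(y))
  if (length(obs) == 0) stop_config("no phenotyped individuals")
  p <- colMeans(Z) / 2
  W <- sweep(Z, 2, 2 * p)
  vy <- stats::var(y[obs])
  if (is.null(scale)) {
    sumhet <- sum(2 * p * (1 - p))
    sb2 <- vy * h2 / max((1 - pi_zero) * sumhet, .Machine$double.eps)
    scale <- if (df > 2) sb2 * (df - 2) / df else sb2
  }
  set.seed(seed)
  fit <- cpp_bayesb(y[obs], W[obs, , drop = FALSE], pi_zero,
                    as.integer(n_iter), as.integer(n_burn), df, scale,
                    max(vy * (1 - h2), .Machine$double.eps), fix_common_var)
  list(ebv = drop(W %*% fit$beta_mean),
       effects = fit$beta_mean,
       inclusion_prob = fit$inclusion_prob,
       mu = fit$mu_mean,
       settings = list(pi_zero = pi_zero, n_iter = n_iter, n_burn = n_burn,
                       df = df, scale = scale))
}
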