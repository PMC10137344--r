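#' Breeding-program configuration
#'
#' Collects and validates every tunable of a simulated breeding scenario.
#' Defaults reproduce the base study design: a historical population of 200
#' (equal sexes) split into two purebred lines selected 10 generations for
#' their own trait (100 and 500 additive QTLs, each calibrated to unit
#' genetic variance), hybridization (A sires x B dams, then B males x F1
#' females) and 5 generations of purebred reproduction with 5 sires and 20
#' dams selected per generation out of 200 candidates.
#'
#' @param founder_n Historical population size (divisible by 4 so the two
#'   purebred lines start with balanced sexes). Also the per-generation
#'   candidate pool size unless `offspring_per_generation` is given.
#' @param offspring_per_generation Offspring per population per generation
#'   (default `founder_n`).
#' @param n_sires,n_dams Parents selected per generation.
#' @param historical_generations,reproduction_generations Phase lengths.
#' @param qtl_counts Length-2 vector of QTL counts for the two traits.
#' @param h2 Heritability for phenotype generation in `(0, 1]`.
#' @param method Selection criterion from the cross onward: one of
#'   `"KIS"`, `"GBLUP"`, `"BayesB"`, `"TBV"`, `"negative_control"`.
#' @param weighting KIS locus weighting, `"equal"` or `"effect"`.
#' @param false_negative_rate Fraction of ideal loci deleted (`[0, 1)`).
#' @param false_positive_rate Fraction of pseudo-positive loci added.
#' @param nonadditive_proportion,nonadditive_mode Share of QTLs given
#'   dominance/epistatic effects (`"none"`, `"dominance"`, `"epistasis"`,
#'   `"both"`).
#' @param n_control_loci Loci in the negative-control ideal (default 600).
#' @param n_chromosomes,chromosome_length,markers_per_chromosome Genome
#'   defaults: 10 chromosomes x 1 Morgan x 500 markers.
#' @param reference_scope Phenotype reference for GBLUP/BayesB:
#'   `"recent"` (default) trains on the most recent phenotyped cohort only
#'   — the limited reference a small breeding program can maintain —
#'   while `"accumulate"` keeps every phenotyped generation of the
#'   running scenario.
#' @param bayesb_pi,bayesb_iter,bayesb_burn,bayesb_df BayesB settings.
#' @param gblup_blend Identity blending weight for the GRM.
#' @param seed Master seed; every sub-stream is derived from it by name.
#' @param scenario_id Free-text label carried into result tables.
#' @return A validated `breeding_config` (named list).
#' @export
breeding_config <- function(founder_n = 200L,
                            offspring_per_generation = NULL,
                            n_sires = 5L,
                            n_dams = 20L,
                            historical_generations = 10L,
                            reproduction_generations = 5L,
                            qtl_counts = c(100L, 500L),
                            h2 = 0.5,
                            method = "KIS",
                            weighting = "equal",
                            false_negative_rate = 0,
                            false_positive_rate = 0,
                            nonadditive_proportion = 0,
                            nonadditive_mode = "none",
                            n_control_loci = 600L,
                            n_chromosomes = 10L,
                            chromosome_length = 1,
                            markers_per_chromosome = 500L,
                            reference_scope = "recent",
                            bayesb_pi = 0.95,
                            bayesb_iter = 2000L,
                            bayesb_burn = 500L,
                            bayesb_df = 4.234,
                            gblup_blend = 0.01,
                            seed = 1L,
                            scenario_id = "base") {
  cfg <- list(founder_n = as.integer(founder_n),
              offspring_per_generation =
                as.integer(offspring_per_generation %||% founder_n),
              n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              historical_generations = as.integer(historical_generations),
              reproduction_generations = as.integer(reproduction_generations),
              qtl_counts = as.integer(qtl_counts), h2 = as.numeric(h2),
              method = method, weighting = weighting,
              false_negative_rate = as.numeric(false_negative_rate),
              false_positive_rate = as.numeric(false_positive_rate),
              nonadditive_proportion = as.numeric(nonadditive_proportion),
              nonadditive_mode = nonadditive_mode,
              n_control_loci = as.integer(n_control_loci),
              reference_scope = reference_scope,
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.numeric(chromosome_length),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              bayesb_pi = as.numeric(bayesb_pi),
              bayesb_iter = as.integer(bayesb_iter),
              bayesb_burn = as.integer(bayesb_burn),
              bayesb_df = as.numeric(bayesb_df),
              gblup_blend = as.numeric(gblup_blend),
              seed = as.integer(seed),
              scenario_id = scenario_id)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (founder_n < 4 || founder_n %% 4 != 0)
      stop_config("founder_n must be a positive multiple of 4 (two ",
                  "purebred lines with balanced sexes)")
    if (n_sires < 1 || n_dams < 1)
      stop_config("n_sires and n_dams must be >= 1")
    if (n_sires > founder_n / 4 || n_dams > founder_n / 4)
      stop_config("cannot select ", n_sires, " sires / ", n_dams,
                  " dams from ", founder_n / 4,
                  " candidates of each sex per line")
    if (offspring_per_generation < 2 || offspring_per_generation %% 2 != 0)
      stop_config("offspring_per_generation must be even and >= 2")
    if (n_sires > offspring_per_generation / 2 ||
        n_dams > offspring_per_generation / 2)
      stop_config("selected parents exceed per-sex candidate pool")
    if (length(qtl_counts) != 2 || any(qtl_counts < 1))
      stop_config("qtl_counts must be two positive counts")
    if (sum(qtl_counts) > n_chromosomes * markers_per_chromosome)
      stop_config("total QTLs exceed marker count")
    if (h2 <= 0 || h2 > 1) stop_config("h2 must lie in (0, 1]")
    if (!method %in% c("KIS", "GBLUP", "BayesB", "TBV", "negative_control"))
      stop_config("unknown method: ", method)
    if (!weighting %in% c("equal", "effect"))
      stop_config("weighting must be 'equal' or 'effect'")
    if (false_negative_rate < 0 || false_negative_rate >= 1)
      stop_config("false_negative_rate must lie in [0, 1)")
    if (false_positive_rate < 0)
      stop_config("false_positive_rate must be >= 0")
    if (!reference_scope %in% c("recent", "accumulate"))
      stop_config("reference_scope must be 'recent' or 'accumulate'")
    if (!nonadditive_mode %in% c("none", "dominance", "epistasis", "both"))
      stop_config("unknown nonadditive_mode: ", nonadditive_mode)
    if (nonadditive_proportion < 0 || nonadditive_proportion > 1)
      stop_config("nonadditive_proportion must lie in [0, 1]")
  })
  structure(cfg, class = "breeding_config")
}

#' @export
print.breeding_config <- function(x, ...) {
  cat("breeding_config", x$scenario_id, ": method", x$method, ",",
      x$founder_n, "founders,", x$n_sires, "sires x", x$n_dams,
      "dams ->", x$offspring_per_generation, "offspring, QTLs",
      paste(x$qtl_counts, collapse = "+"), ", h2", x$h2,
      ", seed", x$seed, "\n")
  invisible(x)
}

#' Load a breeding configuration from a YAML key-value file
#'
#' Unknown keys are rejected; missing keys take their defaults; an empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A `breeding_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_config("cannot parse config ", path, ": ", conditionMessage(e)))
  if (is.null(vals)) vals <- list()
  known <- names(formals(breeding_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_config("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(breeding_config, vals)
}

#' Write a breeding configuration to YAML
#' @param config A `breeding_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
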