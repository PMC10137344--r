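#' Build the scoring context of a scenario
#'
#' Derives from the configuration and the simulated trait architectures
#' everything the selection methods need from the cross onward: the
#' combined two-trait ideal individual (with the configured weighting and
#' any false-negative / pseudo-positive perturbation applied), the
#' negative-control ideal, and the prediction settings.
#'
#' @param config A [breeding_config()].
#' @param genome The genome map.
#' @param traits List of the two `trait_architecture`s.
#' @return A `scenario_context` list.
#' @export
scenario_context <- function(config, genome, traits) {
  ideal <- build_ideal(traits, weighting = config$weighting)
  if (config$false_negative_rate > 0)
    ideal <- false_negative_ideal(ideal, config$false_negative_rate,
                                  seed = derive_seed(config$seed,
                                                     "ideal", "fn"))[[1]]
  if (config$false_positive_rate > 0)
    ideal <- false_positive_ideal(ideal, config$false_positive_rate, genome,
                                  seed = derive_seed(config$seed,
                                                     "ideal", "fp"))
  control <- NULL
  if (config$method == "negative_control")
    control <- negative_control_ideal(genome, traits, config$n_control_loci,
                                      seed = derive_seed(config$seed,
                                                         "ideal", "control"))
  structure(list(config = config, genome = genome, traits = traits,
                 ideal = ideal, control_ideal = control),
            class = "scenario_context")
}

# -- phenotype pool for the comparator methods ------------------------------

pool_init <- function() list(id = character(0), Z = NULL, y = numeric(0),
                             cohort = integer(0))

pool_add <- function(pool, pop, ctx, label, new_cohort = TRUE) {
  g <- genotypic_value(pop, ctx$traits)
  y <- phenotype(g, ctx$config$h2,
                 seed = derive_seed(ctx$config$seed, "phenotype", label))
  co <- if (length(pool$cohort) == 0) 1L
        else if (new_cohort) max(pool$cohort) + 1L else max(pool$cohort)
  pool$id <- c(pool$id, pop$id)
  pool$y <- c(pool$y, y)
  pool$cohort <- c(pool$cohort, rep(co, n_individuals(pop)))
  Z <- genotypes(pop)
  pool$Z <- if (is.null(pool$Z)) Z else rbind(pool$Z, Z)
  pool
}

# restrict the phenotype pool to the configured reference scope
pool_reference <- function(pool, scope) {
  if (scope == "accumulate" || length(pool$cohort) == 0) return(pool)
  keep <- pool$cohort == max(pool$cohort)
  list(id = pool$id[keep], Z = pool$Z[keep, , drop = FALSE],
       y = pool$y[keep], cohort = pool$cohort[keep])
}

needs_pool <- function(method) method %in% c("GBLUP", "BayesB")

# One prediction fit per scoring event; returns a function(pop) -> scores.
# Candidates are selected before they are phenotyped (the genomic-selection
# setting), so any individual in `candidates` that is not already in the
# phenotype pool enters the fit with a missing record and obtains its EBV
# through the markers / genomic relationships alone.
event_scorer <- function(method, ctx, pool, label, candidates = list()) {
  cfg <- ctx$config
  switch(method,
    KIS = function(pop) kis_index(pop, ctx$ideal),
    negative_control = function(pop) kis_index(pop, ctx$control_ideal),
    TBV = function(pop) true_breeding_value(pop, ctx$traits),
    GBLUP = ,
    BayesB = {
      if (length(pool$y) == 0) stop_config("empty phenotype pool")
      pool <- pool_reference(pool, cfg$reference_scope)
      Z <- pool$Z; y <- pool$y; ids <- pool$id
      for (pop in candidates) {
        new <- !(pop$id %in% ids)
        if (any(new)) {
          Z <- rbind(Z, genotypes(pop)[new, , drop = FALSE])
          y <- c(y, rep(NA_real_, sum(new)))
          ids <- c(ids, pop$id[new])
        }
      }
      ebv <- if (method == "GBLUP") {
        gblup_ebv(y, grm_vanraden(Z), cfg$h2, blend = cfg$gblup_blend)
      } else {
        bayesb_ebv(y, Z, pi_zero = cfg$bayesb_pi,
                   n_iter = cfg$bayesb_iter, n_burn = cfg$bayesb_burn,
                   df = cfg$bayesb_df, h2 = cfg$h2,
                   seed = derive_seed(cfg$seed, "bayesb", label))$ebv
      }
      names(ebv) <- ids
      function(pop) unname(ebv[pop$id])
    },
    stop_config("unknown method: ", method))
}

record_rows <- function(pop, label, method, ctx, scores, decision) {
  tbv <- true_breeding_value(pop, ctx$traits)
  sel <- list(M = decision$sire_idx, F = decision$dam_idx)
  rows <- lapply(c("M", "F"), function(s) {
    idx <- sel[[s]]
    all_idx <- which(pop$sex == s)
    data.frame(scenario_id = ctx$config$scenario_id, method = method,
               generation_label = label, sex = s,
               group = c("selected", "all"),
               mean_tbv = c(mean(tbv[idx]), mean(tbv[all_idx])),
               n = c(length(idx), length(all_idx)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# -- historical phase -------------------------------------------------------

#' Run the historical phase: two purebred lines under own-trait KIS
#'
#' The founders are split at random into lines A and B with balanced
#' sexes; each line is selected for its own trait by equal-weight KIS
#' (genotypic similarity to the trait's ideal individual) for
#' `historical_generations` generations, `n_sires` sires x `n_dams` dams
#' producing `offspring_per_generation` offspring per generation,
#' independently per line.
#'
#' @param config A [breeding_config()].
#' @param genome Optional genome map (simulated from the config if `NULL`).
#' @param traits Optional list of two `trait_architecture`s.
#' @param founders Optional founder `population`.
#' @param seed Master seed (default `config$seed`).
#' @return List with `popA`, `popB` (the final generation of each line),
#'   `genome`, `traits`, `founders` and `history` (per-line, per-generation
#'   selected-parent mean TBV records).
#' @export
run_historical_phase <- function(config, genome = NULL, traits = NULL,
                                 founders = NULL, seed = config$seed) {
  if (is.null(genome))
    genome <- make_genome(config$n_chromosomes, config$chromosome_length,
                          config$markers_per_chromosome,
                          seed = derive_seed(seed, "genome"))
  if (is.null(founders))
    founders <- simulate_founders(genome, config$founder_n,
                                  seed = derive_seed(seed, "founders"))
  if (is.null(traits)) {
    t1 <- assign_trait(genome, config$qtl_counts[1], founders,
                       seed = derive_seed(seed, "trait", 1),
                       trait_id = "trait1")
    t2 <- assign_trait(genome, config$qtl_counts[2], founders,
                       exclude_indices = t1$qtl_indices,
                       seed = derive_seed(seed, "trait", 2),
                       trait_id = "trait2")
    traits <- list(t1, t2)
    if (config$nonadditive_proportion > 0 &&
        config$nonadditive_mode != "none")
      traits <- lapply(seq_along(traits), function(i)
        add_nonadditive(traits[[i]], config$nonadditive_proportion,
                        config$nonadditive_mode, founders,
                        seed = derive_seed(seed, "nonadditive", i)))
  }
  # random split into two lines, balanced sexes
  set.seed(derive_seed(seed, "split"))
  males <- sample(which(founders$sex == "M"))
  females <- sample(which(founders$sex == "F"))
  half_m <- length(males) %/% 2; half_f <- length(females) %/% 2
  idxA <- c(males[seq_len(half_m)], females[seq_len(half_f)])
  idxB <- setdiff(seq_len(n_individuals(founders)), idxA)
  lines <- list(A = subset_population(founders, idxA),
                B = subset_population(founders, idxB))
  ideals <- list(A = build_ideal(traits[[1]], "equal"),
                 B = build_ideal(traits[[2]], "equal"))
  history <- list()
  for (ln in c("A", "B")) {
    pop <- lines[[ln]]
    for (g in seq_len(config$historical_generations)) {
      sc <- kis_score(pop, ideals[[ln]])
      dec <- select_parents(sc, pop$sex, config$n_sires, config$n_dams,
                            seed = derive_seed(seed, "hist", ln, g, "sel"))
      tbv <- true_breeding_value(pop, traits)
      history[[length(history) + 1]] <- data.frame(
        line = ln, generation_label = paste0("hist", g - 1),
        mean_tbv_selected = mean(tbv[c(dec$sire_idx, dec$dam_idx)]),
        mean_tbv_all = mean(tbv), stringsAsFactors = FALSE)
      pop <- produce_offspring(subset_population(pop, dec$sire_idx),
                               subset_population(pop, dec$dam_idx),
                               config$offspring_per_generation, genome,
                               paste0("hist", g),
                               seed = derive_seed(seed, "hist", ln, g,
                                                  "mei"),
                               id_prefix = paste0(ln, g))
    }
    lines[[ln]] <- pop
  }
  list(popA = lines$A, popB = lines$B, genome = genome, traits = traits,
       founders = founders, history = do.call(rbind, history))
}

#' Prepare the shared base of a scenario
#'
#' Genome, founders, calibrated traits and the KIS-driven historical phase
#' - everything that is common to all selection methods compared within
#' one replicate (common random numbers).
#'
#' @param config A [breeding_config()].
#' @return The [run_historical_phase()] result.
#' @export
prepare_base <- function(config) run_historical_phase(config)

# -- hybridization + purebred reproduction ----------------------------------

#' Run the hybridization phase
#'
#' F1 = `n_sires` line-A sires x `n_dams` line-B dams; F2 = `n_sires`
#' line-B males x `n_dams` F1 females.  Parents are chosen by the method
#' under test against the combined two-trait objective.  The per-generation
#' record is the mean TBV of the top `n_sires` males and top `n_dams`
#' females *of that generation* under the method's score (for F1 the male
#' group is recorded even though the F2 sires come from line B).
#'
#' @param popA,popB Final-generation populations of the two lines.
#' @param config A [breeding_config()].
#' @param ctx A [scenario_context()].
#' @param method Selection method tag (default `config$method`).
#' @param seed Master seed.
#' @return List with `F1`, `F2` populations, `records` (result rows),
#'   `pool` (accumulated phenotype pool) and `last_decision` (the selected
#'   F2 parents for the reproduction phase).
#' @export
run_hybridization <- function(popA, popB, config, ctx,
                              method = config$method, seed = config$seed) {
  pool <- pool_init()
  if (needs_pool(method)) {
    pool <- pool_add(pool, popA, ctx, "A_final")
    pool <- pool_add(pool, popB, ctx, "B_final", new_cohort = FALSE)
  }
  # F1 cross: A sires x B dams (the line-10 adults are phenotyped)
  scorer <- event_scorer(method, ctx, pool, "cross", list(popA, popB))
  scA <- scorer(popA); scB <- scorer(popB)
  decA <- select_parents(scA, popA$sex, config$n_sires,
                         max(1L, sum(popA$sex == "F")), # sires only used
                         seed = derive_seed(seed, "sel", "crossA"),
                         method_tag = method)
  decB <- select_parents(scB, popB$sex, max(1L, sum(popB$sex == "M")),
                         config$n_dams,
                         seed = derive_seed(seed, "sel", "crossB"),
                         method_tag = method)
  F1 <- produce_offspring(subset_population(popA, decA$sire_idx),
                          subset_population(popB, decB$dam_idx),
                          config$offspring_per_generation, ctx$genome, "F1",
                          seed = derive_seed(seed, "mei", "F1"))
  # F1 record + F2 parents (B males x F1 females); the F1 candidates are
  # not yet phenotyped at selection time
  scorer <- event_scorer(method, ctx, pool, "F1", list(F1, popB))
  scF1 <- scorer(F1)
  decF1 <- select_parents(scF1, F1$sex, config$n_sires, config$n_dams,
                          seed = derive_seed(seed, "sel", "F1"),
                          method_tag = method)
  records <- record_rows(F1, "F1", method, ctx, scF1, decF1)
  scB2 <- scorer(popB)
  decB2 <- select_parents(scB2, popB$sex, config$n_sires,
                          max(1L, sum(popB$sex == "F")),
                          seed = derive_seed(seed, "sel", "F2sires"),
                          method_tag = method)
  F2 <- produce_offspring(subset_population(popB, decB2$sire_idx),
                          subset_population(F1, decF1$dam_idx),
                          config$offspring_per_generation, ctx$genome, "F2",
                          seed = derive_seed(seed, "mei", "F2"))
  if (needs_pool(method)) pool <- pool_add(pool, F1, ctx, "F1")
  scorer <- event_scorer(method, ctx, pool, "F2", list(F2))
  scF2 <- scorer(F2)
  decF2 <- select_parents(scF2, F2$sex, config$n_sires, config$n_dams,
                          seed = derive_seed(seed, "sel", "F2"),
                          method_tag = method)
  records <- rbind(records, record_rows(F2, "F2", method, ctx, scF2, decF2))
  if (needs_pool(method)) pool <- pool_add(pool, F2, ctx, "F2")
  list(F1 = F1, F2 = F2, records = records, pool = pool,
       last_decision = decF2)
}

#' Run the purebred reproduction phase (G1..Gk)
#'
#' Each generation: score all candidates by the method, truncation-select
#' `n_sires` males and `n_dams` females, mate to
#' `offspring_per_generation` offspring, and record the selected groups'
#' mean TBV.
#'
#' @param start Starting `population` (normally F2).
#' @param config A [breeding_config()].
#' @param ctx A [scenario_context()].
#' @param method Method tag (default `config$method`).
#' @param pool Phenotype pool carried over from [run_hybridization()].
#' @param start_decision Selected parents of the starting generation (from
#'   the hybridization phase); computed afresh when `NULL`.
#' @param seed Master seed.
#' @return List with `records` (result rows) and `final` (last
#'   generation's `population`).
#' @export
run_purebred_reproduction <- function(start, config, ctx,
                                      method = config$method,
                                      pool = pool_init(),
                                      start_decision = NULL,
                                      seed = config$seed) {
  pop <- start
  dec <- start_decision
  if (is.null(dec)) {
    scorer <- event_scorer(method, ctx, pool, "start", list(pop))
    sc <- scorer(pop)
    dec <- select_parents(sc, pop$sex, config$n_sires, config$n_dams,
                          seed = derive_seed(seed, "sel", "start"),
                          method_tag = method)
  }
  records <- list()
  for (g in seq_len(config$reproduction_generations)) {
    lab <- paste0("G", g)
    pop <- produce_offspring(subset_population(pop, dec$sire_idx),
                             subset_population(pop, dec$dam_idx),
                             config$offspring_per_generation, ctx$genome,
                             lab, seed = derive_seed(seed, "mei", lab))
    scorer <- event_scorer(method, ctx, pool, lab, list(pop))
    sc <- scorer(pop)
    if (needs_pool(method)) pool <- pool_add(pool, pop, ctx, lab)
    dec <- select_parents(sc, pop$sex, config$n_sires, config$n_dams,
                          seed = derive_seed(seed, "sel", lab),
                          method_tag = method)
    records[[g]] <- record_rows(pop, lab, method, ctx, sc, dec)
  }
  list(records = do.call(rbind, records), final = pop)
}

#' Run one full scenario replicate
#'
#' Historical phase, hybridization and purebred reproduction under the
#' configured method and robustness settings; emits tidy per-generation,
#' per-sex mean-TBV records.
#'
#' @param config A [breeding_config()].
#' @param base Optional pre-computed [prepare_base()] result, so several
#'   methods can share the same genome, traits, founders and historical
#'   phase (common random numbers).
#' @param method Method tag (default `config$method`).
#' @return Data frame with columns `scenario_id`, `method`,
#'   `generation_label` (`F1`, `F2`, `G1`..), `sex`, `group`
#'   (`selected` / `all`), `mean_tbv`, `n`.
#' @export
run_scenario <- function(config, base = NULL, method = config$method) {
  config$method <- method
  if (is.null(base)) base <- prepare_base(config)
  ctx <- scenario_context(config, base$genome, base$traits)
  hyb <- run_hybridization(base$popA, base$popB, config, ctx,
                           method = method)
  rep <- run_purebred_reproduction(hyb$F2, config, ctx, method = method,
                                   pool = hyb$pool,
                                   start_decision = hyb$last_decision)
  rbind(hyb$records, rep$records)
}
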