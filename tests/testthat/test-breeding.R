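test_that("configuration validation catches inconsistent designs", {
  expect_s3_class(breeding_config(), "breeding_config")
  expect_error(breeding_config(n_sires = 0), class = "kisim_config_error")
  expect_error(breeding_config(founder_n = 50), class = "kisim_config_error")
  expect_error(breeding_config(h2 = 0), class = "kisim_config_error")
  expect_error(breeding_config(method = "BLUP"),
               class = "kisim_config_error")
  expect_error(breeding_config(founder_n = 40, n_dams = 11),
               class = "kisim_config_error")
})

test_that("historical phase sizes, labels and selection response", {
  cfg <- tiny_config()
  base <- run_historical_phase(cfg)
  expect_equal(n_individuals(base$popA), 40)
  expect_equal(n_individuals(base$popB), 40)
  expect_equal(unique(base$popA$generation), "hist3")
  expect_equal(sum(base$popA$sex == "M"), 20)
  expect_equal(nrow(base$history), 2 * 3)

  # own-trait KIS selection raises own-trait TBV across the phase
  histA <- base$history[base$history$line == "A", ]
  expect_gt(histA$mean_tbv_all[3], histA$mean_tbv_all[1])

  # the lines diverge: A scores poorly against B's ideal and vice versa
  idealB <- build_ideal(base$traits[[2]])
  expect_lt(mean(kis_score(base$popA, idealB)),
            mean(kis_score(base$popB, idealB)))
})

test_that("hybridization crosses the right parents", {
  cfg <- tiny_config()
  base <- prepare_base(cfg)
  ctx <- scenario_context(cfg, base$genome, base$traits)
  hyb <- run_hybridization(base$popA, base$popB, cfg, ctx)
  expect_true(all(hyb$F1$sire %in% base$popA$id))   # F1 sires from A
  expect_true(all(hyb$F1$dam %in% base$popB$id))    # F1 dams from B
  expect_true(all(hyb$F2$sire %in% base$popB$id))   # F2 sires from B gen-10
  expect_true(all(hyb$F2$dam %in% hyb$F1$id))       # F2 dams from F1
  expect_equal(sum(hyb$F1$sex == "M"), cfg$offspring_per_generation / 2)
  expect_setequal(unique(hyb$records$generation_label), c("F1", "F2"))
})

test_that("complementary fixed parents give fully heterozygous F1
           scoring exactly L", {
  m <- 40
  g <- tiny_genome(n_chr = 2, m = m / 2)
  n <- 16
  popA <- make_pop(matrix(1L, n, m), matrix(1L, n, m), gen = "hist10",
                   ids = paste0("A", 1:n))
  popB <- make_pop(matrix(0L, n, m), matrix(0L, n, m), gen = "hist10",
                   ids = paste0("B", 1:n))
  arch <- make_arch(seq(2, 20, by = 2), rep(1, 10))
  f0 <- make_pop(rbind(matrix(1L, 2, m), matrix(0L, 2, m)),
                 rbind(matrix(1L, 2, m), matrix(0L, 2, m)))
  arch <- kisim:::calibrate_architecture(arch, f0)
  cfg <- breeding_config(founder_n = 16, n_sires = 2, n_dams = 4,
                         offspring_per_generation = 16,
                         qtl_counts = c(5, 5), n_chromosomes = 2,
                         markers_per_chromosome = m / 2)
  ctx <- scenario_context(cfg, g, list(arch))
  hyb <- run_hybridization(popA, popB, cfg, ctx)
  Z <- genotypes(hyb$F1)
  expect_true(all(Z[, arch$qtl_indices] == 1L))      # heterozygous
  L <- nrow(ctx$ideal)
  expect_true(all(kis_score(hyb$F1, ctx$ideal) == L))
})

test_that("purebred reproduction produces labelled balanced generations", {
  cfg <- tiny_config()
  res <- run_scenario(cfg)
  expect_setequal(unique(res$generation_label),
                  c("F1", "F2", "G1", "G2"))
  expect_equal(nrow(res), 4 * 2 * 2)   # labels x sexes x groups
  sel <- res[res$group == "selected", ]
  expect_equal(unique(sel$n[sel$sex == "M"]), cfg$n_sires)
  expect_equal(unique(sel$n[sel$sex == "F"]), cfg$n_dams)
  expect_equal(unique(res$n[res$group == "all"]),
               cfg$offspring_per_generation / 2)
})

test_that("oracle TBV selection dominates any other criterion pointwise", {
  g <- tiny_genome()
  f <- simulate_founders(g, 60, seed = 41)
  arch <- assign_trait(g, 10, f, seed = 42)
  tbv <- true_breeding_value(f, arch)
  ki <- kis_score(f, build_ideal(arch))
  d_tbv <- select_parents(tbv, f$sex, 3, 5, seed = 1)
  d_kis <- select_parents(ki, f$sex, 3, 5, seed = 1)
  expect_gte(mean(tbv[c(d_tbv$sire_idx, d_tbv$dam_idx)]),
             mean(tbv[c(d_kis$sire_idx, d_kis$dam_idx)]))
})

test_that("pedigrees close over the scenario and methods share the base", {
  cfg <- tiny_config()
  base <- prepare_base(cfg)
  ctx <- scenario_context(cfg, base$genome, base$traits)
  hyb <- run_hybridization(base$popA, base$popB, cfg, ctx)
  rep <- run_purebred_reproduction(hyb$F2, cfg, ctx, pool = hyb$pool,
                                   start_decision = hyb$last_decision)
  expect_true(all(rep$final$sire != rep$final$dam))
  # the same base yields bitwise-identical founders on reuse
  base2 <- prepare_base(cfg)
  expect_identical(base$founders$hap1, base2$founders$hap1)
  expect_identical(base$popA$hap1, base2$popA$hap1)
})
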