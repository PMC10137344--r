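test_that("make_genome lays out markers and frequencies as requested", {
  g1 <- make_genome(1, 1, 1, freq_sampler = function(n) rep(0.5, n),
                    seed = 1)
  expect_equal(g1$n_markers, 1L)
  expect_equal(g1$positions, 0)
  expect_equal(g1$founder_freqs, 0.5)

  g <- make_genome(10, 1.0, 500, seed = 7)
  expect_equal(g$n_markers, 5000L)
  expect_equal(as.integer(table(g$chromosome)), rep(500L, 10))
  for (c in 1:10)
    expect_true(all(diff(g$positions[g$chromosome == c]) > 0))
  expect_true(all(g$founder_freqs >= 0.05 & g$founder_freqs <= 0.95))

  expect_identical(make_genome(2, 1, 10, seed = 3),
                   make_genome(2, 1, 10, seed = 3))
  expect_false(identical(make_genome(2, 1, 10, seed = 3)$founder_freqs,
                         make_genome(2, 1, 10, seed = 4)$founder_freqs))
  expect_error(make_genome(0, 1, 10), class = "kisim_config_error")
})

test_that("founder simulation respects sex balance and allele frequencies", {
  g <- tiny_genome()
  f <- simulate_founders(g, 200, seed = 2)
  expect_equal(sum(f$sex == "M"), 100)
  expect_equal(sum(f$sex == "F"), 100)
  expect_true(all((f$hap1 == 0 | f$hap1 == 1) & (f$hap2 == 0 | f$hap2 == 1)))
  expect_error(simulate_founders(g, 201), class = "kisim_config_error")

  gfix <- tiny_genome(freq = 1)
  ffix <- simulate_founders(gfix, 10, seed = 1)
  expect_true(all(genotypes(ffix) == 2L))

  # observed frequency within an exact binomial CI around 0.3
  g3 <- tiny_genome(n_chr = 1, m = 1, freq = 0.3)
  f3 <- simulate_founders(g3, 2000, seed = 5)
  k <- sum(f3$hap1[, 1]) + sum(f3$hap2[, 1])
  ci <- stats::binom.test(k, 4000)$conf.int
  expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
})

test_that("meiosis follows the Haldane model", {
  # zero-length chromosome: gamete is exactly one parental haplotype
  g0 <- tiny_genome(n_chr = 1, len = 0, m = 10)
  h1 <- rep(1L, 10); h2 <- rep(0L, 10)
  gam <- meiosis(h1, h2, g0, seed = 3)
  expect_true(identical(gam, h1) || identical(gam, h2))

  # fully homozygous parent: gamete forced
  g1 <- tiny_genome(n_chr = 1, len = 1, m = 10)
  expect_identical(meiosis(h1, h1, g1, seed = 4), h1)

  # recombinant fraction between two markers d apart matches
  # (1 - exp(-2d)) / 2 within 3 binomial standard errors at 1e5 gametes
  d <- 0.2
  gm <- make_genome(1, d, 2, freq_sampler = function(n) rep(0.5, n))
  parent <- make_pop(matrix(1L, 1, 2), matrix(0L, 1, 2))
  set.seed(11)
  gams <- kisim:::make_gametes(parent, rep(1L, 1e5), gm)
  rec <- mean(gams[, 1] != gams[, 2])
  r_true <- (1 - exp(-2 * d)) / 2
  expect_lt(abs(rec - r_true), 3 * sqrt(r_true * (1 - r_true) / 1e5))
})

test_that("offspring production is balanced, sexed and Mendelian", {
  g <- tiny_genome()
  f <- simulate_founders(g, 200, seed = 2)
  sires <- subset_population(f, which(f$sex == "M")[1:5])
  dams <- subset_population(f, which(f$sex == "F")[1:20])
  off <- produce_offspring(sires, dams, 200, g, "G1", seed = 9)
  expect_equal(n_individuals(off), 200)
  expect_equal(sum(off$sex == "M"), 100)
  expect_equal(as.integer(table(off$dam)), rep(10L, 20))   # 10 per dam
  expect_equal(as.integer(table(off$sire)), rep(40L, 5))   # 4 dams x 10 each
  expect_true(all(off$dam %in% dams$id))
  expect_true(all(off$sire %in% sires$id))

  pair <- produce_offspring(subset_population(f, 1), subset_population(f, 2),
                            2, g, "x", seed = 1)
  expect_equal(unique(pair$sire), f$id[1])
  expect_equal(unique(pair$dam), f$id[2])

  # exhaustive Mendelian consistency on a small cross
  for (i in seq_len(n_individuals(pair))) {
    expect_true(all(pair$hap1[i, ] == f$hap1[1, ] |
                      pair$hap1[i, ] == f$hap2[1, ]))
    expect_true(all(pair$hap2[i, ] == f$hap1[2, ] |
                      pair$hap2[i, ] == f$hap2[2, ]))
  }
  expect_error(produce_offspring(sires, dams, 3, g, "x"),
               class = "kisim_config_error")
})

test_that("trait assignment calibrates founder TBV variance to exactly 1", {
  g <- make_genome(10, 1, 500, seed = 7)
  f <- simulate_founders(g, 200, seed = 2)
  t1 <- assign_trait(g, 100, f, seed = 3, trait_id = "trait1")
  t2 <- assign_trait(g, 500, f, exclude_indices = t1$qtl_indices, seed = 4,
                     trait_id = "trait2")
  expect_equal(var(true_breeding_value(f, t1)), 1, tolerance = 1e-12)
  expect_equal(var(true_breeding_value(f, t2)), 1, tolerance = 1e-12)
  expect_length(union(t1$qtl_indices, t2$qtl_indices), 600)
  expect_error(assign_trait(g, 5001, f), class = "kisim_config_error")
})

test_that("single-QTL pre-scaling variance matches 2p(1-p)a^2", {
  p <- 0.3
  g <- tiny_genome(n_chr = 1, m = 1, freq = p)
  f <- simulate_founders(g, 20000, seed = 8)
  arch <- assign_trait(g, 1, f, effect_sampler = function(n) rep(1, n),
                       seed = 1)
  var_raw <- 1 / arch$scale^2      # calibration divides by raw sd
  expect_equal(var_raw, 2 * p * (1 - p), tolerance = 0.02)
})

test_that("non-additive effects are added, counted and recalibrated", {
  g <- tiny_genome(m = 100)
  f <- simulate_founders(g, 200, seed = 2)
  arch <- assign_trait(g, 100, f, seed = 3)
  expect_identical(add_nonadditive(arch, 0, "dominance", f), arch)

  ad <- add_nonadditive(arch, 0.1, "dominance", f, seed = 5)
  expect_equal(sum(ad$dominance != 0), 10)
  expect_equal(var(genotypic_value(f, ad)), 1, tolerance = 1e-12)

  ae <- add_nonadditive(arch, 0.2, "epistasis", f, seed = 5)
  expect_equal(nrow(ae$epistasis), 20)
  members <- c(ae$epistasis[, "qtl1"], ae$epistasis[, "qtl2"])
  expect_length(unique(members), 40)
  expect_true(all(members %in% ae$qtl_indices))
  expect_error(add_nonadditive(arch, 1.2, "both", f),
               class = "kisim_config_error")
})

test_that("TBV is the scaled dosage-effect dot product and is linear", {
  arch <- make_arch(1:3, c(0.5, -1, 2))
  Z <- matrix(c(2, 1, 0), 1, 3)
  expect_equal(true_breeding_value(Z, arch), 2 * 0.5 + 1 * (-1) + 0 * 2)
  expect_equal(true_breeding_value(matrix(0, 1, 3), arch), 0)
  arch2 <- make_arch(1:3, 2 * c(0.5, -1, 2))
  Zr <- matrix(sample(0:2, 30, TRUE), 10, 3)
  expect_equal(true_breeding_value(Zr, arch2),
               2 * true_breeding_value(Zr, arch))
  expect_error(true_breeding_value(matrix(0, 1, 2), arch))
})

test_that("genotypic value adds dominance/epistasis and reduces to TBV", {
  arch <- make_arch(1:4, c(1, -0.5, 0.25, 2))
  Z <- matrix(sample(0:2, 40, TRUE), 10, 4)
  expect_equal(genotypic_value(Z, arch), true_breeding_value(Z, arch))

  d_arch <- make_arch(1, 0, d = 0.4)
  expect_equal(genotypic_value(matrix(1, 1, 1), d_arch), 0.4)

  # brute-force term-by-term oracle on a random instance
  set.seed(42)
  epi <- cbind(qtl1 = c(1, 3), qtl2 = c(2, 5), effect = c(0.3, -0.7))
  full <- make_arch(1:5, rnorm(5), d = rnorm(5), epi = epi, scale = 1.7)
  Z <- matrix(sample(0:2, 50, TRUE), 10, 5)
  oracle <- sapply(seq_len(10), function(i) {
    v <- sum(Z[i, ] * full$additive) +
      sum(full$dominance[Z[i, full$qtl_indices] == 1])
    for (r in 1:2)
      v <- v + epi[r, 3] * (Z[i, epi[r, 1]] - 1) * (Z[i, epi[r, 2]] - 1)
    v * full$scale
  })
  expect_equal(genotypic_value(Z, full), unname(oracle))
})

test_that("phenotypes carry the configured heritability", {
  gv <- rnorm(50)
  expect_identical(phenotype(gv, 1, seed = 1), gv)
  expect_identical(phenotype(gv, 0.5, seed = 2), phenotype(gv, 0.5, seed = 2))
  expect_error(phenotype(gv, 0), class = "kisim_config_error")

  set.seed(3)
  g <- rnorm(20000)
  y <- phenotype(g, 0.5, seed = 4)
  fit <- lm(y ~ g)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(summary(fit)$r.squared, 0.5, tolerance = 0.05)
})
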