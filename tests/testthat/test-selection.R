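test_that("build_ideal encodes beneficial alleles, weights and subsystems", {
  arch <- make_arch(c(2, 5, 9), c(0.4, -0.3, 0), scale = 2)
  ideal <- build_ideal(arch)
  expect_equal(ideal$locus, c(2L, 5L))       # zero-effect locus dropped
  expect_equal(ideal$allele, c(1L, 0L))      # sign rule
  expect_equal(ideal$weight, c(1, 1))
  idw <- build_ideal(arch, weighting = "effect")
  expect_equal(idw$weight, abs(c(0.4, -0.3)) * 2)

  g <- make_genome(10, 1, 500, seed = 7)
  f <- simulate_founders(g, 100, seed = 2)
  t1 <- assign_trait(g, 100, f, seed = 3, trait_id = "trait1")
  t2 <- assign_trait(g, 500, f, exclude_indices = t1$qtl_indices, seed = 4,
                     trait_id = "trait2")
  both <- build_ideal(list(t1, t2))
  expect_equal(nrow(both), 600)
  expect_setequal(unique(both$subsystem), c("trait1", "trait2"))
})

test_that("kis_score assigns 0/1/2 per locus and matches the loop oracle", {
  L <- 7
  ideal <- kisim:::new_ideal(1:L, rep(1L, L), rep(1, L), "t")
  expect_equal(kis_score(matrix(2L, 1, L), ideal), 2 * L)   # maximum
  expect_equal(kis_score(matrix(1L, 1, L), ideal), L)       # heterozygote
  expect_equal(kis_score(matrix(0L, 1, L), ideal), 0)

  i3 <- kisim:::new_ideal(1:3, c(1L, 1L, 1L), c(1, 1, 1), "t")
  expect_equal(kis_score(matrix(c(2L, 0L, 1L), 1, 3), i3), 3)

  set.seed(10)
  for (rep in 1:100) {
    m <- sample(3:12, 1)
    n <- sample(1:6, 1)
    L <- sample(seq_len(m), sample(seq_len(m), 1))
    ideal <- kisim:::new_ideal(L, rbinom(length(L), 1, 0.5),
                               runif(length(L), 0, 2),
                               sample(c("a", "b"), length(L), TRUE))
    Z <- matrix(sample(0:2, n * m, TRUE), n, m)
    expect_equal(kis_score(Z, ideal), kis_oracle(Z, ideal))
    tot <- rowSums(kis_score(Z, ideal, by_subsystem = TRUE))
    expect_equal(unname(tot), kis_oracle(Z, ideal))
  }
})

test_that("kis_score is monotone in beneficial-allele substitutions", {
  set.seed(11)
  m <- 20
  ideal <- kisim:::new_ideal(1:m, rbinom(m, 1, 0.5), runif(m), "t")
  for (rep in 1:50) {
    Z <- matrix(sample(0:2, m, TRUE), 1, m)
    s0 <- kis_score(Z, ideal)
    j <- sample(m, 1)
    Z2 <- Z
    if (ideal$allele[j] == 1) Z2[1, j] <- min(2, Z[1, j] + 1)
    else Z2[1, j] <- max(0, Z[1, j] - 1)
    expect_gte(kis_score(Z2, ideal), s0)
  }
})

test_that("kis_index normalizes subsystem scores to equal importance", {
  # single subsystem: same ranking as the raw score
  set.seed(12)
  ideal <- kisim:::new_ideal(1:10, rbinom(10, 1, 0.5), rep(1, 10), "t")
  Z <- matrix(sample(0:2, 80, TRUE), 8, 10)
  expect_equal(order(kis_index(Z, ideal)), order(kis_score(Z, ideal)))
  # two subsystems of unequal size contribute equally
  id2 <- kisim:::new_ideal(1:6, rep(1L, 6), rep(1, 6),
                           c("a", rep("b", 5)))
  z_a <- matrix(c(2L, rep(0L, 5)), 1, 6)  # perfect on a, zero on b
  z_b <- matrix(c(0L, rep(2L, 5)), 1, 6)  # zero on a, perfect on b
  expect_equal(kis_index(z_a, id2), kis_index(z_b, id2))
  expect_equal(kis_index(z_a, id2), 0.5)
})

test_that("false-negative deletions are nested across rates", {
  ideal <- kisim:::new_ideal(1:100, rep(1L, 100), rep(1, 100), "t")
  out <- false_negative_ideal(ideal, c(0, 0.1, 0.2, 0.3), seed = 5)
  expect_identical(out[[1]]$locus, ideal$locus)        # rate 0: identity
  expect_equal(nrow(out[[4]]), 70)
  miss <- lapply(out, function(x) setdiff(ideal$locus, x$locus))
  expect_true(all(miss[[2]] %in% miss[[3]]))
  expect_true(all(miss[[3]] %in% miss[[4]]))
  expect_error(false_negative_ideal(ideal, c(0.5, 1)),
               class = "kisim_config_error")
})

test_that("pseudo-positive loci are adjacent, novel and inherit subsystems", {
  g <- tiny_genome(n_chr = 2, m = 100)
  f <- simulate_founders(g, 50, seed = 2)
  arch <- assign_trait(g, 100, f, seed = 3)
  ideal <- build_ideal(arch)
  expect_identical(false_positive_ideal(ideal, 0, g), ideal)
  fp <- false_positive_ideal(ideal, 0.1, g, seed = 6)
  expect_equal(nrow(fp), 110)
  added <- setdiff(fp$locus, ideal$locus)
  expect_length(added, 10)
  expect_true(all(sapply(added, function(a)
    min(abs(a - ideal$locus)) <= 1)))
  expect_false(any(duplicated(fp$locus)))
  expect_true(all(fp$subsystem %in% ideal$subsystem))

  # nested across rates when the seed (perturbation stream) is shared
  fp3 <- false_positive_ideal(ideal, 0.3, g, seed = 6)
  expect_true(all(added %in% fp3$locus))
})

test_that("negative-control ideals avoid all QTLs and carry no signal", {
  g <- make_genome(10, 1, 500, seed = 7)
  f <- simulate_founders(g, 200, seed = 2)
  t1 <- assign_trait(g, 100, f, seed = 3)
  t2 <- assign_trait(g, 500, f, exclude_indices = t1$qtl_indices, seed = 4)
  ctrl <- negative_control_ideal(g, list(t1, t2), seed = 5)
  expect_equal(nrow(ctrl), 600)
  expect_length(intersect(ctrl$locus,
                          c(t1$qtl_indices, t2$qtl_indices)), 0)
  r <- cor(kis_score(f, ctrl), true_breeding_value(f, list(t1, t2)))
  expect_lt(abs(r), 3 / sqrt(200))
})

test_that("truncation selection takes the top of each sex, ties seeded", {
  scores <- c(5, 4, 3, 2, 1, 10, 9, 8, 7, 6)
  sexes <- rep(c("M", "F"), each = 5)
  dec <- select_parents(scores, sexes, 2, 2, seed = 1)
  expect_equal(sort(dec$sire_idx), c(1, 2))
  expect_equal(sort(dec$dam_idx), c(6, 7))

  # all-tied scores: reproducible random subset
  tied <- rep(1, 10)
  d1 <- select_parents(tied, sexes, 2, 2, seed = 7)
  d2 <- select_parents(tied, sexes, 2, 2, seed = 7)
  expect_identical(d1$sire_idx, d2$sire_idx)

  # min selected >= max unselected within sex (no ties)
  set.seed(13)
  sc <- sample(seq(0.1, 10, by = 0.1), 40)
  sx <- rep(c("M", "F"), 20)
  d <- select_parents(sc, sx, 5, 5, seed = 2)
  expect_gte(min(sc[d$sire_idx]),
             max(sc[setdiff(which(sx == "M"), d$sire_idx)]))
  expect_gte(min(sc[d$dam_idx]),
             max(sc[setdiff(which(sx == "F"), d$dam_idx)]))
  expect_error(select_parents(sc, sx, 30, 5), class = "kisim_config_error")
})
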