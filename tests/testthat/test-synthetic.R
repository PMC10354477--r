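test_that("sim_params validates its inputs", {
  expect_error(sim_params(seed = NULL), "seed")
  expect_error(sim_params(n_breeding_females = 0, seed = 1))
  expect_error(sim_params(immigration_rate = 1.5, seed = 1))
  expect_error(sim_params(litter_size = "two", seed = 1), "litter_size")
  expect_error(sim_params(paternity = "harem", seed = 1), "paternity")
  p <- sim_params(litter_size = list(lambda = 2.5), seed = 1)
  expect_equal(p$litter_size$type, "poisson")
})

test_that("simulator realizes the three ground-truth regimes", {
  # single founding line, no immigration -> RELATED
  s <- simulate_unit_pedigree(sim_params(
    n_breeding_females = 1, litter_size = 2, n_generations = 2,
    immigration_rate = 0, sex_ratio = 1, seed = 11))
  expect_equal(s$truth$F, "RELATED")
  expect_equal(
    classify_composition(s$pedigree, s$units$F, "permissive")$label, "RELATED")

  # two unrelated matrilines retained alongside an immigrant -> MIX_RELATED
  s2 <- simulate_unit_pedigree(sim_params(
    n_breeding_females = 2, litter_size = 2, n_generations = 1,
    immigration_rate = 1, paternity = list(n_sires = 2), sex_ratio = 1,
    seed = 12))
  expect_equal(s2$truth$F, "MIX_RELATED")
  expect_equal(
    classify_composition(s2$pedigree, s2$units$F, "permissive")$label,
    "MIX_RELATED")

  # founders only -> UNRELATED
  s0 <- simulate_unit_pedigree(sim_params(
    n_breeding_females = 3, n_generations = 0, seed = 13))
  expect_equal(s0$truth$F, "UNRELATED")
  expect_equal(
    classify_composition(s0$pedigree, s0$units$F, "permissive")$label,
    "UNRELATED")
})

test_that("identical seeds give identical simulations, files included", {
  p <- sim_params(n_breeding_females = 2, litter_size = list(lambda = 2),
                  n_generations = 2, immigration_rate = 0.5,
                  paternity = list(n_sires = 2), seed = 77)
  s1 <- simulate_unit_pedigree(p)
  s2 <- simulate_unit_pedigree(p)
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  s3 <- simulate_unit_pedigree(sim_params(
    n_breeding_females = 2, litter_size = list(lambda = 2),
    n_generations = 2, immigration_rate = 0.5,
    paternity = list(n_sires = 2), seed = 78))
  expect_false(identical(as.data.frame(s1$pedigree), as.data.frame(s3$pedigree)))
})

test_that("noisy_relatedness is unbiased, exact at sd 0, and seed-stable", {
  s <- simulate_unit_pedigree(sim_params(
    n_breeding_females = 2, litter_size = 3, n_generations = 2,
    paternity = list(n_sires = 2), sex_ratio = 1, seed = 5))
  ids <- s$units$F$members
  ev0 <- noisy_relatedness(s$pedigree, ids, sd = 0, seed = 9)
  r <- relatedness_matrix(s$pedigree, ids)
  expect_equal(ev0$evidence$r_hat,
               r[cbind(ev0$evidence$i, ev0$evidence$j)])
  expect_identical(noisy_relatedness(s$pedigree, ids, 0.05, seed = 4),
                   noisy_relatedness(s$pedigree, ids, 0.05, seed = 4))
  # law of large numbers: mean bias of r_hat - r over many dyads ~ 0
  big <- random_pedigree(30, 606)
  evb <- noisy_relatedness(big, big$id, sd = 0.05, seed = 31)
  nb <- nrow(evb$evidence)
  rb <- relatedness_matrix(big)[cbind(evb$evidence$i, evb$evidence$j)]
  resid <- evb$evidence$r_hat - rb
  expect_lt(abs(mean(resid)), 3 * stats::sd(resid) / sqrt(nb))
})

test_that("cluster rule recovers mixedness from noisy two-matriline data", {
  # two matrilines of half/full sibs (within-line r >= 0.25), unrelated
  # across lines; epsilon = 0.1 splits the two expectations, allowing for
  # the Gaussian noise that makes a between-line mean of exactly 0
  # unattainable with the literal epsilon = 0
  hits <- 0L
  for (k in 1:200) {
    s <- simulate_unit_pedigree(sim_params(
      n_breeding_females = 2, litter_size = 3, n_generations = 1,
      paternity = list(n_sires = 50), sex_ratio = 1, seed = 9000 + k))
    u <- s$units$F
    ev <- noisy_relatedness(s$pedigree, u$members, sd = 0.05, seed = 9000 + k)
    res <- classify_from_clusters(ev$evidence, u, ev$lines, epsilon = 0.1)
    hits <- hits + (res$label == "MIX_RELATED")
  }
  expect_gte(hits, 190)  # >= 95% of 200 noisy replicates
})

test_that("binary trait simulation obeys the symmetric chain", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(unname(simulate_binary_trait(tr, q = 0, root_state = 1,
                                            seed = 1)),
               c(1L, 1L, 1L))
  trn <- ape::rtree(4)
  trn$edge.length <- NULL
  expect_error(simulate_binary_trait(trn, 1, 1, seed = 1), "branch length")
  # single branch: P(flip) = (1 - exp(-2qt))/2
  one <- ape::read.tree(text = "(A:1.5,B:0.0001);")
  q <- 0.6
  flips <- vapply(1:4000, function(k) {
    st <- simulate_binary_trait(one, q, root_state = 0, seed = 20000 + k)
    unname(st["A"])
  }, 1L)
  p_hat <- mean(flips)
  p_true <- 0.5 * (1 - exp(-2 * q * 1.5))
  se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_lt(abs(p_hat - p_true), 3 * se)
  # saturation: q * depth = 10 -> tip frequency at the stationary 1/2
  deep <- ape::read.tree(text = "(A:10,B:10);")
  states <- vapply(1:1000, function(k)
    unname(simulate_binary_trait(deep, 1, root_state = 0,
                                 seed = 30000 + k)["A"]), 1L)
  expect_lt(abs(mean(states) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("composition fractions track litter size and immigration", {
  # Paper-direction sign check: monotocy and immigration both push units
  # away from fully-related; the not-fully-related fraction must be
  # non-increasing in litter size and non-decreasing in immigration.
  frac_notrel <- function(litter, imm, reps = 60) {
    labs <- vapply(seq_len(reps), function(r) {
      s <- simulate_unit_pedigree(sim_params(
        n_breeding_females = 3, litter_size = litter, n_generations = 2,
        immigration_rate = imm, paternity = list(n_sires = 50),
        sex_ratio = 1, seed = 100000 + 10000 * litter + 1000 * round(10 * imm) + r))
      if (!is_social_unit(s$units$F)) NA_character_ else s$truth$F
    }, "")
    mean(labs != "RELATED", na.rm = TRUE)
  }
  m <- outer(c(1, 2, 4), c(0, 0.4, 0.8), Vectorize(frac_notrel))
  for (row in 1:3) expect_true(all(diff(m[row, ]) >= 0))  # immigration up
  for (col in 1:3) expect_true(all(diff(m[, col]) <= 0))  # litter size up
})
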