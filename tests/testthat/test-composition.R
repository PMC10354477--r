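test_that("filter_social_unit keeps same-sex adults and flags non-units", {
  members <- data.frame(
    id = c(paste0("f", 1:4), "m1", paste0("y", 1:3)),
    sex = c(rep("F", 4), "M", "F", "M", "F"),
    age_class = c(rep("adult", 5), rep("immature", 3)),
    stringsAsFactors = FALSE)
  # one adult male: no same-sex adults for him to be (un)related to
  um <- filter_social_unit(members, "M")
  expect_false(is_social_unit(um))
  expect_s3_class(um, "kincomp_not_a_unit")
  uf <- filter_social_unit(members, "F")
  expect_true(is_social_unit(uf))
  expect_length(uf$members, 4)
  u2 <- filter_social_unit(data.frame(id = c("a", "b"), sex = "F"), "F")
  expect_length(u2$members, 2)  # >= 2 boundary
  dup <- data.frame(id = c("a", "a"), sex = c("F", "M"), age_class = "adult")
  expect_error(filter_social_unit(dup, "F"), "contradictory")
  # consistent duplicates collapse silently
  dup2 <- data.frame(id = c("a", "a", "b"), sex = "F", age_class = "adult")
  expect_length(filter_social_unit(dup2, "F")$members, 2)
})

test_that("classify_composition labels the worked trios correctly", {
  cous <- cousin_trio_pedigree()
  u <- social_unit("cousins", c("x1", "x2", "x3"), "F")
  res <- classify_composition(cous, u, "permissive")
  expect_equal(res$label, "RELATED")
  expect_equal(res$proportion_kin, 1)
  expect_equal(res$mean_r, 0.125)

  mixed <- mixed_trio_pedigree()
  u2 <- social_unit("mixed", c("X", "H", "C"), "F")
  res2 <- classify_composition(mixed, u2, "permissive")
  expect_equal(res2$label, "MIX_RELATED")
  expect_equal(res2$proportion_kin, 2 / 3)
  expect_equal(res2$mean_r, 0.125)
  expect_equal(res2$n_kin + res2$n_nonkin + res2$n_undetermined, 3)

  founders <- pedigree(id = c("a", "b"), sex = c("F", "F"))
  res3 <- classify_composition(founders, social_unit("u", c("a", "b"), "F"),
                               "permissive")
  expect_equal(res3$label, "UNRELATED")
  expect_equal(res3$proportion_kin, 0)
  # strict policy surfaces the same unit as INCONCLUSIVE
  res4 <- classify_composition(founders, social_unit("u", c("a", "b"), "F"),
                               "strict")
  expect_equal(res4$label, "INCONCLUSIVE")
  expect_true(is.na(res4$proportion_kin))
  expect_error(
    classify_composition(mixed, social_unit("u", c("X", "nope"), "F")),
    "absent.*nope")
})

test_that("mean_relatedness averages over all dyads", {
  mixed <- mixed_trio_pedigree()
  expect_equal(
    mean_relatedness(mixed, social_unit("u", c("X", "H", "C"), "F")),
    (0.25 + 0.125 + 0) / 3)
  founders <- pedigree(id = c("a", "b", "c"))
  expect_equal(mean_relatedness(founders, social_unit("u", c("a", "b", "c"), "F")), 0)
})

test_that("composition refines mean relatedness and respects small-unit laws", {
  # the two Introduction-style trios: same mean r, different labels
  m1 <- classify_composition(cousin_trio_pedigree(),
                             social_unit("a", c("x1", "x2", "x3"), "F"),
                             "permissive")
  m2 <- classify_composition(mixed_trio_pedigree(),
                             social_unit("b", c("X", "H", "C"), "F"),
                             "permissive")
  expect_equal(m1$mean_r, m2$mean_r)
  expect_false(m1$label == m2$label)
  # a unit of two has a single dyad, so it can never be MIX_RELATED
  for (seed in 1:10) {
    ped <- random_pedigree(12, seed + 300)
    ids <- sample(ped$id, 2)
    res <- classify_composition(ped, social_unit("u", ids, "F"), "permissive")
    expect_true(res$label != "MIX_RELATED")
  }
  # exactly one label, counts conserved
  for (seed in 1:6) {
    ped <- random_pedigree(15, seed + 400)
    ids <- sample(ped$id, 5)
    res <- classify_composition(ped, social_unit("u", ids, "F"), "strict")
    expect_equal(res$n_kin + res$n_nonkin + res$n_undetermined, 10)
    expect_true(res$label %in% c("RELATED", "UNRELATED", "MIX_RELATED",
                                 "INCONCLUSIVE"))
    if (res$n_undetermined > 0) expect_equal(res$label, "INCONCLUSIVE")
  }
})

test_that("classify_from_clusters applies the two-cluster rule", {
  u <- social_unit("u", c("a1", "a2", "b1", "b2"), "F")
  lines <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  ev <- data.frame(
    i = c("a1", "a1", "a1", "a2", "a2", "b1"),
    j = c("a2", "b1", "b2", "b1", "b2", "b2"),
    r_hat = c(0.30, -0.02, 0.01, -0.03, 0.00, 0.26))
  res <- classify_from_clusters(ev, u, lines)
  expect_equal(res$label, "MIX_RELATED")
  cm <- attr(res, "cluster_means")
  expect_equal(unname(cm$within["A"]), 0.30)
  expect_equal(unname(cm$within["B"]), 0.26)
  expect_lt(cm$between, 0.005)

  # all means positive: cannot certify both cluster types
  ev2 <- ev; ev2$r_hat <- abs(ev2$r_hat) + 0.05
  expect_equal(classify_from_clusters(ev2, u, lines)$label, "INCONCLUSIVE")
  # within-line means at zero: no certified related cluster
  ev3 <- ev; ev3$r_hat[c(1, 6)] <- 0
  expect_equal(classify_from_clusters(ev3, u, lines)$label, "INCONCLUSIVE")
  expect_error(classify_from_clusters(ev, u, c(a1 = "A", a2 = "A", b1 = "A",
                                               b2 = "A")), ">= 2 line")
  expect_error(classify_from_clusters(ev[-2, ], u, lines), "missing.*a1-b1")
})

test_that("raising epsilon never converts INCONCLUSIVE to MIX_RELATED", {
  u <- social_unit("u", c("a1", "a2", "b1", "b2"), "F")
  lines <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  set.seed(42)
  for (rep in 1:20) {
    ev <- data.frame(i = c("a1", "a1", "a1", "a2", "a2", "b1"),
                     j = c("a2", "b1", "b2", "b1", "b2", "b2"),
                     r_hat = stats::rnorm(6, 0.1, 0.2))
    labs <- vapply(c(0, 0.05, 0.15, 0.3), function(eps)
      classify_from_clusters(ev, u, lines, epsilon = eps)$label, "")
    # once inconclusive because no positive within-cluster remains, larger
    # epsilon cannot resurrect MIX via the within test
    mix <- labs == "MIX_RELATED"
    within_max <- max(mean(ev$r_hat[c(1)]), mean(ev$r_hat[6]))
    if (!mix[1] && within_max <= 0) expect_false(any(mix))
  }
})

test_that("unit table reader and composition writer round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,period,individual_id,sex,age_class",
               "u1,2020,x1,F,adult", "u1,2020,x2,F,adult"), f)
  tab <- load_unit_table(f)
  expect_equal(nrow(tab), 2)
  g <- withr::local_tempfile(fileext = ".csv")
  res <- classify_composition(cousin_trio_pedigree(),
                              social_unit("cousins", c("x1", "x2", "x3"), "F",
                                          period = "2020"),
                              "permissive")
  write_composition(res, g)
  back <- utils::read.csv(g, stringsAsFactors = FALSE)
  expect_equal(back$label, "RELATED")
  expect_equal(back$mean_r, 0.125)
})
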