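test_that("drug-set keys are unordered and reject self-pairs", {
  expect_identical(drug_set_key(c("B", "A")), drug_set_key(c("A", "B")))
  expect_error(drug_set_key(c("A", "A")), "must differ")
  expect_error(drug_set_key(character(0)), "1 or 2")
  expect_identical(format(drug_set_key(c("zeta", "alpha"))), "alpha + zeta")
})

test_that("collect_instances pools all instances of the key's molecules", {
  comp <- tiny_compendium(list(c(1L, 2L, 3L), c(3L, 2L, 1L), c(2L, 1L, 3L)),
                          c("A", "A", "B"))
  expect_setequal(collect_instances(comp, drug_set_key(c("A", "B"))),
                  c("i1", "i2", "i3"))
  expect_setequal(collect_instances(comp, drug_set_key("A")), c("i1", "i2"))
  expect_error(collect_instances(comp, drug_set_key("Aa")), "unknown molecule")
})

test_that("drug_set_es is the KS statistic on instance positions", {
  ordered <- paste0("i", 1:10)
  expect_equal(drug_set_es(ordered, c("i1", "i2")), 0.8)
  expect_equal(drug_set_es(ordered, c("i9", "i10")), -0.9)
  # members = all profiles: no enrichment possible beyond 1/m
  expect_lte(abs(drug_set_es(ordered, ordered)), 1 / 10 + 1e-12)
  expect_error(drug_set_es(ordered, "zz"), "no member instance")
})

test_that("permutation p-value agrees with exhaustive subset enumeration", {
  ordered <- paste0("i", 1:6)
  obs <- drug_set_es(ordered, c("i1", "i2"))
  # exact two-sided null over all 15 size-2 subsets
  null <- apply(combn(6, 2), 2, function(s) oracle_ks(s, 6))
  p_exact <- mean(abs(null) >= abs(obs))
  n_perm <- 4000
  p_hat <- permutation_pvalue(ordered, 2, obs, n_perm = n_perm, seed = 99)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_hat - p_exact), 3 * se + 2 / n_perm)

  # add-one floor and reproducibility
  p_floor <- permutation_pvalue(paste0("i", 1:50), 5, 0.999,
                                n_perm = 1000, seed = 1)
  expect_equal(p_floor, 1 / 1001)
  expect_identical(permutation_pvalue(ordered, 2, obs, 500, seed = 7),
                   permutation_pvalue(ordered, 2, obs, 500, seed = 7))
  # a central observation is never significant under a symmetric null
  expect_gte(permutation_pvalue(ordered, 2, 0, 500, seed = 3), 0.5)
})

test_that("score_drug_sets is key-symmetric, deterministic, and flags plants", {
  fx <- pair_recovery_fixture(seed = 7, n_molecules = 8,
                              instances_per_molecule = 5)
  conn <- pathway_connectivity(fx$compendium, reverse_signature(fx$signature),
                               fx$pathways[c("PW01", "PW02")])
  keys <- list(drug_set_key(c("drugA", "drugB")),
               drug_set_key(c("drugB", "drugA")),
               drug_set_key("drugA"))
  s_ab <- score_drug_sets(fx$compendium, conn, keys[1], n_perm = 500, seed = 11)
  s_ba <- score_drug_sets(fx$compendium, conn, keys[2], n_perm = 500, seed = 11)
  expect_identical(s_ab, s_ba)
  s2 <- score_drug_sets(fx$compendium, conn, keys, n_perm = 500, seed = 11)
  s2b <- score_drug_sets(fx$compendium, conn, keys, n_perm = 500, seed = 11)
  expect_identical(s2, s2b)
  # planted single drug: strongly positive and significant in its pathway
  a_p1 <- s2[s2$key == "drugA" & s2$pathway_id == "PW01", ]
  expect_gt(a_p1$set_es, 0.5)
  expect_true(a_p1$significant)
  expect_identical(score_drug_sets(fx$compendium, conn, list(), 100, seed = 1),
                   score_drug_sets(fx$compendium, conn, list(), 100, seed = 2))
})

test_that("rank_candidates counts strict threshold crossings and breaks ties", {
  scores <- data.frame(
    key = rep(c("a + x", "b + y", "c + z"), each = 3),
    pathway_id = rep(c("P1", "P2", "P3"), 3),
    set_size = 4L,
    set_es = c(0.9, 0.8, 0.7,   0.6, 0.9, 0.5,   0.2, -0.6, 0),
    p_value = rep(0.001, 9),
    n_permutations = 1000L,
    significant = TRUE, stringsAsFactors = FALSE)
  rk <- rank_candidates(scores, mode = "pair")
  expect_identical(rk$key, c("a + x", "b + y", "c + z"))
  expect_identical(rk$n_positive, c(3L, 2L, 0L))      # es = 0.5 not counted
  expect_identical(rk$negative_pathways[3], "P2")
  expect_identical(rk$rank, 1:3)

  # all-zero scores: lexicographic order
  zero <- scores; zero$set_es <- 0
  expect_identical(rank_candidates(zero, mode = "pair")$key,
                   sort(unique(scores$key)))

  # non-significant pathways are not counted by default
  ns <- scores; ns$p_value <- 0.5; ns$significant <- FALSE
  expect_true(all(rank_candidates(ns, mode = "pair")$n_positive == 0))
  expect_identical(rank_candidates(ns, mode = "pair", require_significance = FALSE)$n_positive,
                   c(3L, 2L, 0L))

  single <- scores; single$key <- rep(c("a", "b", "c"), each = 3)
  expect_identical(rank_candidates(single, mode = "single")$n_positive[1], 3L)
  expect_error(rank_candidates(single, mode = "pair"), "not of mode")
  expect_error(rank_candidates(rbind(scores, single), mode = "pair"), "mixed")
})

test_that("enumerate_pairs builds all unordered pairs with optional filter", {
  p <- enumerate_pairs(c("a", "b", "c", "d"))
  expect_length(p, 6)
  expect_length(enumerate_pairs(c("a", "b", "c", "d"), filter = c("a", "b")), 1)
  expect_error(enumerate_pairs(c("a", "b"), filter = "a"), "at least 2")
})
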