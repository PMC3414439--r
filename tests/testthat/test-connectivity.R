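test_that("ks_score reproduces hand-derived values and the enumeration oracle", {
  expect_equal(ks_score(1L, 10), 0.9)
  expect_equal(ks_score(c(1L, 2L), 10), 0.8)
  expect_equal(ks_score(c(9L, 10L), 10), -0.9)
  expect_error(ks_score(integer(0), 10), "empty tag")
  expect_error(ks_score(c(2L, 1L), 10), "strictly increasing")

  # exhaustive agreement for n <= 8 here (n <= 12 in the acceptance suite)
  for (n in 1:8) {
    for (s in all_subsets(n)) {
      expect_equal(ks_score(s, n), oracle_ks(s, n),
                   label = sprintf("n=%d tags={%s}", n, paste(s, collapse = ",")))
    }
  }
})

test_that("reversing the ranked list negates ks_score (up to the tie branch)", {
  # reversal swaps the two running-difference sequences up to a 1/n lattice
  # shift, so the score negates to within 1/n away from the a ~= b tie region
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    t <- sample.int(n, 1)
    s <- sort(sample.int(n, t))
    j <- seq_len(t)
    a <- max(j / t - s / n); b <- max(s / n - (j - 1) / t)
    if (abs(a - b) <= 2 / n) next
    fwd <- ks_score(s, n)
    rev <- ks_score(sort(n + 1L - s), n)
    expect_lt(abs(rev + fwd), 1 / n + 1e-12)
  }
})

test_that("profile_es combines directional scores by the opposite-sign rule", {
  n <- 20L
  col <- structure(1:20, names = paste0("g", 1:20))
  # up tags at top, down tags at bottom: strong positive connectivity
  sig <- expr_signature(up = paste0("g", 1:3), down = paste0("g", 18:20))
  r <- profile_es(sig, NULL, col)
  expect_true(r$evaluable)
  expect_gt(r$ks_up, 0); expect_lt(r$ks_down, 0)
  expect_equal(r$raw_es, r$ks_up - r$ks_down)
  expect_gt(r$raw_es, 0)

  # same-sign scores zero out
  sig2 <- expr_signature(up = paste0("g", 1:3), down = paste0("g", 4:6))
  r2 <- profile_es(sig2, NULL, col)
  expect_gt(r2$ks_up, 0); expect_gt(r2$ks_down, 0)
  expect_equal(r2$raw_es, 0)

  # pathway restriction: tags shrink to members, full-length ranks kept
  r3 <- profile_es(sig, c("g1", "g2", "g19", "g20"), col)
  expect_equal(r3$ks_up, ks_score(1:2, 20))
  expect_equal(r3$ks_down, ks_score(19:20, 20))

  # empty restricted side -> not evaluable
  r4 <- profile_es(sig, c("g1", "g2"), col)
  expect_false(r4$evaluable)

  # set semantics: order of the probe lists is irrelevant
  sig_shuffled <- expr_signature(up = rev(sig$up), down = sample(sig$down))
  expect_equal(profile_es(sig_shuffled, NULL, col)$raw_es, r$raw_es)
})

test_that("normalize_es scales per sign class and preserves signs and zeros", {
  expect_equal(normalize_es(c(0.9, -0.45, 0.3, 0)),
               c(1, -1, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(normalize_es(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(normalize_es(0.37), 1)
  set.seed(1)
  raw <- runif(50, -1, 1)
  norm <- normalize_es(raw)
  expect_identical(sign(norm), sign(raw))
  expect_true(all(abs(norm) <= 1))
  # order preserved within each sign class
  expect_identical(order(norm[raw > 0]), order(raw[raw > 0]))
})

test_that("rank_profiles sorts by descending ES with lexicographic ties", {
  tab <- data.frame(instance_id = c("A", "B", "C"), es = c(0.5, -0.2, 0.9))
  expect_identical(rank_profiles(tab), c("C", "A", "B"))
  tied <- data.frame(instance_id = c("z", "a", "m"), es = c(0.1, 0.1, 0.1))
  expect_identical(rank_profiles(tied), c("a", "m", "z"))
  expect_length(rank_profiles(tab), nrow(tab))
})

test_that("pathway_connectivity scores every evaluable profile per pathway", {
  fx <- pair_recovery_fixture(seed = 7, n_molecules = 6,
                              instances_per_molecule = 5)
  conn <- pathway_connectivity(fx$compendium, reverse_signature(fx$signature),
                               fx$pathways[c("PW01", "PW02")])
  expect_setequal(unique(conn$pathway_id), c("PW01", "PW02"))
  expect_true(all(abs(conn$es) <= 1 + 1e-12))
  # same-sign rule holds row-wise
  agree <- sign(conn$ks_up) == sign(conn$ks_down) & conn$ks_up != 0
  expect_true(all(conn$raw_es[agree] == 0))
  # planted reverser tops its pathway under reverse orientation
  p1 <- conn[conn$pathway_id == "PW01", ]
  top <- rank_profiles(p1)[1:5]
  meta <- fx$compendium$metadata
  expect_true(all(meta$molecule_name[match(top, meta$instance_id)] == "drugA"))
})
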