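test_that("generators are seed-deterministic", {
  expect_identical(gen_pathways(10, c(10, 30), 1000, seed = 7),
                   gen_pathways(10, c(10, 30), 1000, seed = 7))
  c1 <- gen_compendium(100, c("a", "b"), 3, seed = 5)
  c2 <- gen_compendium(100, c("a", "b"), 3, seed = 5)
  expect_identical(c1$ranks, c2$ranks)
  expect_identical(c1$metadata, c2$metadata)
  expect_false(identical(c1$ranks, gen_compendium(100, c("a", "b"), 3, seed = 6)$ranks))
})

test_that("gen_pathways respects disjointness and feasibility", {
  pw <- gen_pathways(10, c(10, 30), 1000, overlap = 0, seed = 3)
  expect_length(pw, 10)
  all_members <- unlist(pw)
  expect_identical(anyDuplicated(all_members), 0L)
  expect_error(gen_pathways(10, c(200, 200), 1000, overlap = 0, seed = 1),
               "disjoint")
  expect_error(gen_pathways(2, c(10, 2000), 1000), "exceeds the universe")
})

test_that("unplanted compendium columns are valid uniform permutations", {
  comp <- gen_compendium(200, paste0("m", 1:4), 3, seed = 9)
  n <- nrow(comp$ranks)
  expect_true(all(apply(comp$ranks, 2, function(c) identical(sort(unname(c)), 1:n))))
  # mean rank of a fixed probe across many null columns is near (n+1)/2
  big <- gen_compendium(50, paste0("m", 1:30), 4, seed = 10)
  expect_equal(mean(big$ranks[1, ]), (50 + 1) / 2, tolerance = 0.15)
})

test_that("planting moves signature probes to the intended rank extremes", {
  pw <- gen_pathways(4, c(20, 20), 500, seed = 21)
  sig <- gen_disease_signature(pw, "PW01", size = 30, purity = 1, seed = 22)
  comp <- gen_compendium(500, c("hit", "null"), 4, pathways = pw,
                         plants = list(plant_spec("hit", "PW01", "reverse",
                                                  strength = 1)),
                         disease_signature = sig, noise = 0, seed = 23)
  meta <- comp$metadata
  hit_cols <- meta$instance_id[meta$molecule_name == "hit"]
  up_in <- intersect(sig$up, pw[["PW01"]])
  down_in <- intersect(sig$down, pw[["PW01"]])
  for (ic in hit_cols) {
    col <- comp$ranks[, ic]
    # reverse: disease-up probes at the bottom, disease-down at the top
    expect_true(all(col[up_in] > 500 - length(up_in) - length(down_in)))
    expect_true(all(col[down_in] <= length(down_in)))
  }
  # profile-level ES of planted instances sits at the extreme
  conn <- pathway_connectivity(comp, reverse_signature(sig), pw["PW01"])
  planted <- conn$instance_id %in% hit_cols
  expect_true(min(conn$raw_es[planted]) > max(conn$raw_es[!planted]))
})

test_that("gen_disease_signature concentrates in the perturbed pathways", {
  pw <- gen_pathways(8, c(25, 40), 1000, seed = 31)
  sig <- gen_disease_signature(pw, "PW03", size = 40, purity = 1, seed = 32)
  res <- select_pathways(sig, pw, attr(pw, "universe"))
  expect_identical(res$pathway_id[1], "PW03")
  expect_true(res$selected[1])
  expect_error(gen_disease_signature(pw, "PW03", size = 0), ">= 1")
  expect_error(gen_disease_signature(pw, "nope", size = 10), "unknown perturbed")
  expect_warning(gen_disease_signature(pw, "PW03", up_fraction = 1,
                                       size = 20, seed = 1),
                 "empty")
})

test_that("extract_signature applies inclusive fold-change and p cuts", {
  set.seed(44)
  n <- 60
  ctrl <- matrix(rnorm(n * 4, mean = 10, sd = 0.01), nrow = n,
                 dimnames = list(paste0("g", 1:n), NULL))
  case <- ctrl + rnorm(n * 4, 0, 0.01)
  case[1, ] <- ctrl[1, ] * 4          # planted 4-fold up, tiny variance
  case[2, ] <- ctrl[2, ] / 4
  case[3, ] <- ctrl[3, ] * 2          # exactly 2-fold: inclusive
  sig <- extract_signature(case, ctrl)
  expect_true("g1" %in% sig$up)
  expect_true("g2" %in% sig$down)
  expect_true("g3" %in% sig$up)
  # identical groups -> empty signature
  empty <- extract_signature(ctrl, ctrl)
  expect_length(c(empty$up, empty$down), 0)
  expect_error(extract_signature(ctrl[, 1, drop = FALSE], ctrl), "2 replicates")
})

test_that("dose-response generators invert exactly in the noiseless limit", {
  tab <- gen_dose_response(3, 1.2, c(0.5, 1, 3, 9, 27))
  fit <- median_effect(tab)
  expect_equal(unname(coef(fit)), c(3, 1.2), tolerance = 1e-10)
  expect_error(gen_dose_response(-1, 2, c(1, 2)), "Dm > 0")
  fit_a <- median_effect(gen_dose_response(1, 2, c(0.25, 0.5, 1, 2, 4)))
  expect_error(gen_combo_table(fit_a, fit_a, 0.5, ci_target = -1,
                               doses = c(1, 2)), "ci_target")
})
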