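# shared fixtures: a small noise-free library and five quick models
scr_lib <- generate_library(synthetic_config(n_molecules = 120, seed = 33))
scr_split <- stratified_split(scr_lib, seed = 6)
scr_grid <- enumerate_grid(list(
  n_estimators = 25L, max_depth = c(2L, 4L), learning_rate = 0.1,
  colsample_bytree = 0.9, reg_lambda = 0.01, min_child_weight = 7))
scr_models <- lapply(names(fp_schemes()), function(s) {
  train_with_constraint(scr_lib, scr_split, s, grid = scr_grid, seed = 8)$model
})

test_that("AD criteria are validated", {
  expect_error(ad_criteria(mw_min = 700, mw_max = 200))
  expect_error(ad_criteria(tc_threshold = 0))
  expect_error(ad_criteria(k_neighbors = 0))
  crit <- ad_criteria()
  expect_equal(crit$mw_min, 200)
  expect_equal(crit$mw_max, 700)
  expect_equal(crit$k_neighbors, 5L)
  expect_equal(crit$tc_threshold, 0.4)
})

test_that("the AD filter applies both criteria with reported reasons", {
  # malic acid: parses fine but is far below the 200 Da floor
  cands <- make_library(c(malic = "OC(CC(=O)O)C(=O)O",
                          self = scr_lib$smiles[1]))
  out <- ad_filter(cands, scr_lib)
  malic <- out[out$candidate_id == "malic", ]
  expect_false(malic$ad_pass)
  expect_true(malic$mw_out_of_range)
  expect_equal(malic$mw, average_molecular_weight("C4H6O5"), tolerance = 1e-6)
  # an exact copy of a training molecule contributes similarity 1 to itself
  self <- out[out$candidate_id == "self", ]
  expect_gte(self$mean_top_k_tc, 1 / 5)
  expect_false(self$low_neighbor_similarity)
})

test_that("mean top-k similarity equals the sort-and-average oracle", {
  cands <- generate_screening_set(synthetic_config(n_molecules = 120, seed = 33),
                                  scr_lib, n_per_stratum = 5)
  crit <- ad_criteria()
  out <- ad_filter(cands, scr_lib, crit)
  cand_fps <- encode_fingerprints(cands, crit$reference_scheme)
  train_fps <- encode_fingerprints(scr_lib, crit$reference_scheme)
  for (i in seq_len(nrow(cands))) {
    sims <- vapply(seq_len(nrow(scr_lib)), function(j) {
      tanimoto(cand_fps[i, ], train_fps[j, ])
    }, 0)
    oracle <- mean(sort(sims, decreasing = TRUE)[1:5])
    expect_equal(out$mean_top_k_tc[out$candidate_id == cands$id[i]], oracle)
  }
})

test_that("the AD filter is monotone in its thresholds", {
  cands <- generate_screening_set(synthetic_config(n_molecules = 120, seed = 34),
                                  scr_lib, n_per_stratum = 6)
  n_pass <- function(crit) sum(ad_filter(cands, scr_lib, crit)$ad_pass)
  base <- n_pass(ad_criteria())
  for (tc in c(0.5, 0.7, 0.9)) {
    expect_lte(n_pass(ad_criteria(tc_threshold = tc)), base)
  }
  for (win in list(c(250, 650), c(300, 500), c(350, 400))) {
    expect_lte(n_pass(ad_criteria(mw_min = win[1], mw_max = win[2])), base)
  }
})

test_that("an unencodable candidate is out of domain, not dropped", {
  cands <- make_library(c(ok = scr_lib$smiles[1]))
  cands <- rbind(cands, data.frame(
    id = "broken", name = NA, smiles = "xx", canonical_key = NA_character_,
    formula = NA_character_, label = "unknown", source = NA))
  verdicts <- consensus_screen(cands, scr_models, scr_lib)
  broken <- verdicts[verdicts$candidate_id == "broken", ]
  expect_identical(broken$consensus, "out_of_domain")
  expect_true(broken$encoding_failure)
  expect_true(is.na(broken$n_active_votes))
})

test_that("consensus flips only at the three-vote majority boundary", {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  for (r in seq_len(nrow(patterns))) {
    votes <- unlist(patterns[r, ])
    n <- sum(votes)
    verdict <- xovscreen:::.vote_consensus(n, TRUE)
    expect_identical(verdict, if (n >= 3) "active" else "not_active")
    for (k in 1:5) {
      flipped <- votes
      flipped[k] <- !flipped[k]
      v2 <- xovscreen:::.vote_consensus(sum(flipped), TRUE)
      crosses <- (n >= 3) != (sum(flipped) >= 3)
      expect_identical(v2 != verdict, crosses)
    }
  }
  expect_identical(xovscreen:::.vote_consensus(5, FALSE), "out_of_domain")
})

test_that("consensus screening wires votes to verdicts", {
  cands <- generate_screening_set(synthetic_config(n_molecules = 120, seed = 33),
                                  scr_lib, n_per_stratum = 5)
  verdicts <- consensus_screen(cands, scr_models, scr_lib)
  expect_equal(nrow(verdicts), nrow(cands))
  in_dom <- verdicts$ad_pass
  expect_true(all(verdicts$consensus[!in_dom] == "out_of_domain"))
  expect_true(all(is.na(verdicts$n_active_votes[!in_dom])))
  expect_identical(verdicts$consensus[in_dom] == "active",
                   verdicts$n_active_votes[in_dom] >= 3)
  # sorted by vote count then id
  v <- verdicts$n_active_votes[in_dom]
  expect_true(all(diff(v) <= 0))
  # duplicate scheme rejected
  expect_error(consensus_screen(cands, scr_models[c(1, 1, 2, 3, 4)], scr_lib),
               "five")
})

test_that("decoy validation is reproducible and counts recoveries", {
  d1 <- decoy_validation(scr_models, scr_lib, n_decoys = 5, seed = 31)
  d2 <- decoy_validation(scr_models, scr_lib, n_decoys = 5, seed = 31)
  expect_identical(d1$decoy_ids, d2$decoy_ids)
  expect_true(all(d1$per_model_recovered <= 5))
  expect_error(decoy_validation(scr_models, scr_lib, n_decoys = 1e4),
               "pool")
})
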