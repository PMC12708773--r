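test_that("exactly five scheme values are legal", {
  schemes <- fp_schemes()
  expect_length(schemes, 5L)
  expect_identical(names(schemes),
                   c("MACCS-167", "ECFP4-1024", "ECFP4-2048",
                     "ECFP6-1024", "ECFP6-2048"))
  expect_error(fp_scheme("MACCS", 1024), "illegal")
  expect_error(fp_scheme("ECFP4", 167), "illegal")
  expect_error(fp_scheme("ECFP2", 1024))
})

test_that("encoding is deterministic with the contracted length", {
  for (s in names(fp_schemes())) {
    f1 <- encode_fingerprints("c1ccccc1", s)
    f2 <- encode_fingerprints("c1ccccc1", s)
    expect_identical(f1, f2)
    expect_identical(ncol(f1), fp_schemes()[[s]]$n_bits)
  }
  methane <- encode_fingerprints("C", "ECFP4-1024")
  expect_gte(sum(methane), 1)
  expect_identical(ncol(methane), 1024L)
})

test_that("tanimoto matches direct evaluation on constructed vectors", {
  a <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  # |A n B| = 2, |A u B| = 8
  expect_equal(tanimoto(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                        c(1, 1, 0, 0, 0, 1, 1, 1, 0, 0)), 0.25)
  expect_warning(z <- tanimoto(numeric(4), numeric(4)), "all-zero")
  expect_equal(z, 1.0)
  fa <- encode_fingerprints("CCO", "ECFP4-1024")
  fb <- encode_fingerprints("CCO", "ECFP4-2048")
  expect_error(tanimoto(fa[1, ], fb[1, ]), "mismatch")
})

test_that("tanimoto equals the set-counting oracle on random pairs", {
  set.seed(42)
  for (n_bits in c(167L, 1024L, 2048L)) {
    for (i in 1:70) {
      a <- random_bits(n_bits, runif(1, 0.02, 0.3))
      b <- random_bits(n_bits, runif(1, 0.02, 0.3))
      expect_equal(tanimoto(a, b), tanimoto_oracle(a, b))
    }
  }
  # and on real encodings, symmetric, self-similarity 1
  fps <- encode_fingerprints(unname(tiny_smiles()), "ECFP6-2048")
  for (i in 1:7) for (j in (i + 1):8) {
    tij <- tanimoto(fps[i, ], fps[j, ])
    expect_equal(tij, tanimoto_oracle(fps[i, ], fps[j, ]))
    expect_equal(tij, tanimoto(fps[j, ], fps[i, ]))
  }
  expect_equal(diag(tanimoto_matrix(fps)), rep(1, 8), ignore_attr = TRUE)
})

test_that("tanimoto_matrix agrees with elementwise tanimoto", {
  fps <- encode_fingerprints(unname(tiny_smiles())[1:5], "MACCS-167")
  tm <- tanimoto_matrix(fps)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(tm[i, j], tanimoto(fps[i, ], fps[j, ]))
  }
})

test_that("diversity profile counts all unordered pairs", {
  trip <- make_library(c(a = "c1ccccc1O", b = "Oc1ccccc1", c = "c1cc(O)ccc1"))
  prof <- diversity_profile(trip, "ECFP4-1024", threshold = 0.4)
  expect_equal(prof$n_pairs, 3L)
  expect_equal(prof$fraction_below, 0)  # all copies, Tc = 1
  expect_equal(sum(prof$histogram), prof$n_pairs)

  two <- make_library(c(x = "CCCCC", y = "c1ccc2ncccc2c1"))
  prof2 <- diversity_profile(two, "ECFP4-1024", threshold = 0.4)
  expect_equal(prof2$n_pairs, 1L)
  expect_equal(prof2$fraction_below, 1)

  lib <- make_library(unname(tiny_smiles()))
  prof3 <- diversity_profile(lib, "ECFP6-1024")
  expect_equal(prof3$n_pairs, choose(8, 2))
  expect_equal(sum(prof3$histogram), prof3$n_pairs)
  expect_error(diversity_profile(lib[1, ]), "at least 2")
})
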