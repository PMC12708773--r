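test_that("curation collapses duplicates and counts encoding failures", {
  rec <- data.frame(
    id = paste0("r", 1:5),
    smiles = c("c1ccccc1O", "CCO", "Oc1ccccc1", "CCC", "CCCC"),
    label = c("active", "inactive", "active", "inactive", "inactive"))
  cur <- curate(rec)
  expect_equal(cur$report$n_retained, 4L)
  expect_equal(cur$report$n_duplicates_removed, 1L)
  expect_identical(cur$library$id, c("r1", "r2", "r4", "r5"))  # first wins
  expect_identical(cur$report$removals$id, "r3")

  bad <- data.frame(id = "x", smiles = "zz_not_smiles", label = "active")
  cur2 <- curate(bad)
  expect_equal(cur2$report$n_encoding_failures, 1L)
  expect_equal(cur2$report$n_retained, 0L)
  expect_equal(cur2$report$n_input - cur2$report$n_duplicates_removed -
                 cur2$report$n_encoding_failures, cur2$report$n_retained)
})

test_that("curation rejects conflicting labels on duplicate structures", {
  rec <- data.frame(id = c("p", "q"),
                    smiles = c("c1ccccc1O", "Oc1ccccc1"),
                    label = c("active", "inactive"))
  expect_error(curate(rec), "p.*q|conflicting")
  expect_error(curate(data.frame(id = "a", smiles = "C", label = "unknown")),
               "unknown")
  expect_error(curate(data.frame()), "non-empty")
})

test_that("a 483-compound library splits 337/73/73", {
  lib <- fake_library(483, active_fraction = 0.45)
  split <- stratified_split(lib, seed = 5)
  expect_length(split$train_ids, 337L)
  expect_length(split$validation_ids, 73L)
  expect_length(split$test_ids, 73L)
  expect_setequal(c(split$train_ids, split$validation_ids, split$test_ids),
                  lib$id)
})

test_that("a balanced 100-compound library splits 70/15/15 per class", {
  lib <- fake_library(100, active_fraction = 0.5)
  split <- stratified_split(lib, seed = 9)
  expect_length(split$train_ids, 70L)
  expect_length(split$validation_ids, 15L)
  expect_length(split$test_ids, 15L)
  for (p in c("validation", "test")) {
    cc <- split$class_counts[[p]]
    expect_true(all(cc %in% 7:8))
  }
})

test_that("splits are reproducible and stratified across random sizes", {
  lib <- fake_library(240, 0.45)
  s1 <- stratified_split(lib, seed = 123)
  s2 <- stratified_split(lib, seed = 123)
  expect_identical(s1, s2)
  s3 <- stratified_split(lib, seed = 124)
  expect_false(identical(s1$test_ids, s3$test_ids))

  set.seed(77)
  for (n in sample(20:1000, 20)) {
    frac <- runif(1, 0.3, 0.7)
    lib <- fake_library(n, frac)
    if (any(table(lib$label) < 3)) next
    sp <- stratified_split(lib, seed = n)
    held <- ceiling(0.15 * n)
    expect_length(sp$test_ids, held)
    expect_length(sp$validation_ids, held)
    expect_length(sp$train_ids, n - 2 * held)
    glob <- table(lib$label) / n
    for (p in names(sp$class_counts)) {
      cc <- sp$class_counts[[p]]
      sz <- sum(cc)
      for (cl in names(glob)) {
        expect_lte(abs(cc[[cl]] / sz - glob[[cl]]), 1 / sz + 1e-12)
      }
    }
  }
})

test_that("split rejects degenerate inputs", {
  lib <- fake_library(40, 0.5)
  expect_error(stratified_split(lib, fractions = c(0.8, 0.1, 0.2)), "sum")
  lib$label <- "active"
  expect_error(stratified_split(lib), "two classes")
  lib2 <- fake_library(40, 0.04)  # 2 actives only
  expect_error(stratified_split(lib2), "at least 3")
})
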