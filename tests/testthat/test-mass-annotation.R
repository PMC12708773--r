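test_that("adduct m/z reproduces printed values at three decimals", {
  expect_equal(round(adduct_mz("C7H6O5", "[M-H]-"), 3), 169.014)    # gallic acid
  expect_equal(round(adduct_mz("C27H22O18", "[M-H]-"), 3), 633.073) # strictinin
  expect_equal(round(adduct_mz("C15H12O5", "[M-H]-"), 3), 271.061)  # naringenin
  expect_equal(round(adduct_mz("C21H20O11", "[M-H]-"), 3), 447.093) # luteolin-7-O-glucoside
  expect_equal(round(adduct_mz("C21H22O11", "[M+Cl]-"), 3), 485.085) # pyracanthoside
  expect_equal(round(adduct_mz("C4H6O5", "[2M+Na-2H]-"), 3), 289.017) # malic acid
  # unicode minus / superscript markup is tolerated
  expect_equal(adduct_mz("C7H6O5", "[M−H]−"),
               adduct_mz("C7H6O5", "[M-H]-"))
})

test_that("adduct arithmetic satisfies its algebraic identities", {
  set.seed(3)
  for (i in 1:30) {
    f <- c(C = sample(1:30, 1), H = sample(1:40, 1), O = sample(1:20, 1))
    mh <- adduct_mz(f, "[M-H]-")
    expect_lt(mh, monoisotopic_mass(f))
    # 2M + Na - 2H  ==  2 (M - H) + Na
    dimer <- adduct_mz(f, "[2M+Na-2H]-")
    expect_equal(dimer, 2 * mh + monoisotopic_mass(c(Na = 1)),
                 tolerance = 1e-9)
  }
  # electron-mass convention shifts a singly charged anion by ~0.00055
  expect_equal(adduct_mz("C7H6O5", "[M-H]-", include_electron = TRUE) -
                 adduct_mz("C7H6O5", "[M-H]-"), 0.000548579909,
               tolerance = 1e-9)
})

test_that("adduct errors are structured", {
  expect_error(adduct_mz("C7H6O5", "[M+H]+"), "unsupported")
  expect_error(adduct_mz("CCl4", "[M-H]-"), "remove more")
  expect_error(adduct_mz("C2F6", "[2M+Na-2H]-"), "remove more")
})

test_that("ppm errors follow the definition and the display rounding", {
  expect_equal(ppm_error(169.014, 169.014), 0)
  theo <- 169.0142468
  expect_equal(round(ppm_error(theo * (1 + 5e-7), theo), 2), 0.50)
  expect_equal(round(ppm_error(theo * (1 + 4e-9), theo), 2), 0.00)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("the shipped annotation tables annotate completely", {
  t1 <- read_annotation_table(extdata("bsubcupularis_metabolites.csv"))
  t2 <- read_annotation_table(extdata("btobiracola_metabolites.csv"))
  expect_equal(nrow(t1), 23L)
  expect_equal(nrow(t2), 21L)
  a1 <- annotate_table(t1)
  a2 <- annotate_table(t2)
  expect_equal(nrow(a1), 23L)
  expect_equal(nrow(a2), 21L)
  expect_identical(a1$name, t1$name)  # order preserved
  # the two extracts share compounds: 33 unique names across 44 rows
  expect_equal(length(unique(c(t1$name, t2$name))), 33L)
  # convention-insensitive 0.00-ppm rows reproduce the printed m/z
  for (nm in c("gallic acid", "strictinin", "naringenin")) {
    row <- a1[a1$name == nm, ][1, ]
    expect_equal(round(row$theoretical_mz, 3), row$measured_mz)
  }
  lut <- a2[a2$name == "luteolin-7-O-glucoside", ]
  expect_equal(round(lut$theoretical_mz, 3), 447.093)
  expect_true(attr(a1, "n_within_5ppm") >= 20)

  bad <- t1[1, ]
  bad$adduct <- "[M+H]+"
  expect_error(annotate_table(bad), "row 1.*unsupported|unsupported")
  expect_error(annotate_table(t1[, -2]), NA)  # extra columns optional
  expect_error(annotate_table(data.frame(name = "x")), "missing column")
})
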