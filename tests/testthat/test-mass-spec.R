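test_that("compositions follow residue, end-group and label bookkeeping", {
  comp <- oligo_composition("CACUCCG", "hydroxyl", "linear-phosphate")
  heavy <- oligo_composition("CACUCCG", "hydroxyl", "linear-phosphate",
                             channel = "heavy", scheme = label_scheme("T1"))
  expect_equal(heavy[["C13"]], 10)                       # one G, 13C10
  expect_equal(heavy[["C12"]], comp[["C12"]] - 10)
  # light vs heavy differ only in the carbon pools
  expect_equal(comp[c("H", "N", "O", "P")], heavy[c("H", "N", "O", "P")])
  # pseudouridine is mass-silent
  psi <- oligo_composition("UAG", mods = data.frame(
    position = 1, mod_type = "pseudouridine"))
  expect_identical(psi, oligo_composition("UAG"))
  # methylation adds exactly +1 C +2 H wherever it sits
  for (p in 1:3) {
    m <- oligo_composition("UAG", mods = data.frame(
      position = p, mod_type = "2'-O-methyl"))
    expect_equal(m - oligo_composition("UAG"),
                 c(C12 = 1, C13 = 0, H = 2, N = 0, O = 0, P = 0))
  }
  expect_error(oligo_composition("UAG", mods = data.frame(
    position = 9, mod_type = "2'-O-methyl")), "outside fragment")
  expect_error(oligo_composition("UAG", channel = "heavy"), "label scheme")
})

test_that("monoisotopic masses agree with the per-atom summation oracle", {
  expect_equal(monoisotopic_mass(c(C12 = 0)), 0)
  set.seed(3)
  for (i in 1:25) {
    s <- random_rna(sample(2:12, 1))
    got <- monoisotopic_mass(oligo_composition(s, "hydroxyl",
                                               "linear-phosphate"))
    expect_lt(abs(got - oracle_oligo_mass(s, extra_phosphates = 1)), 1e-4)
  }
  # heavy shift of one 13C10-G
  l <- monoisotopic_mass(oligo_composition("CACUCCG"))
  h <- monoisotopic_mass(oligo_composition("CACUCCG", channel = "heavy",
                                           scheme = label_scheme("T1")))
  expect_equal(h - l, 10 * 1.0033548, tolerance = 1e-6)
})

test_that("negative-mode m/z and the observable window behave as defined", {
  expect_equal(mz_negative(1000, 1), 1000 - 1.00727646)
  expect_error(mz_negative(1000, 0), "charge")
  mass7 <- monoisotopic_mass(oligo_composition("CACUCCG", "hydroxyl",
                                               "linear-phosphate"))
  expect_true(2L %in% observable_charges(mass7))   # the reported 2- form
  expect_identical(observable_charges(300), integer())
})

test_that("heavy-light shift equals label count x base count for both schemes", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_rna(sample(3:10, 1))
    bases <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "U")))
    for (nm in c("T1", "A")) {
      sch <- label_scheme(nm)
      l <- monoisotopic_mass(oligo_composition(s))
      h <- monoisotopic_mass(oligo_composition(s, channel = "heavy",
                                               scheme = sch))
      expect_equal(h - l, sum(sch * bases) * 1.0033548378, tolerance = 1e-9)
    }
  }
})

test_that("mass additivity holds when splitting at a phosphodiester", {
  # mass(AB) + water = mass(A with 3'-p) + mass(B with 5'-OH), with AB
  # carrying 5'-OH / 3'-OH
  water <- 18.0105646859
  set.seed(8)
  for (i in 1:15) {
    s <- random_rna(sample(4:12, 1))
    k <- sample(2:(nchar(s) - 2), 1)
    ab <- monoisotopic_mass(oligo_composition(s))
    a <- monoisotopic_mass(oligo_composition(substr(s, 1, k),
                                             "hydroxyl", "linear-phosphate"))
    b <- monoisotopic_mass(oligo_composition(substr(s, k + 1, nchar(s))))
    expect_equal(ab + water, a + b, tolerance = 1e-9)
  }
})

test_that("base-permuted fragments are exact isobars", {
  a <- oligo_composition("CACUCCG", "hydroxyl", "linear-phosphate")
  b <- oligo_composition("ACCCCUG", "hydroxyl", "linear-phosphate")
  expect_identical(a, b)
  for (z in 1:5) {
    expect_identical(mz_negative(monoisotopic_mass(a), z),
                     mz_negative(monoisotopic_mass(b), z))
  }
})

test_that("MS2 ladders satisfy counting, closure and methyl additivity", {
  # a 2-mer has one backbone position: 4 series entries per charge
  two <- ms2_ladders("AG", max_charge = 3)
  expect_equal(nrow(two), 4 * 3)
  # series closure: c_i + y_(n-i) = precursor + water
  s <- "CACUCCG"
  water <- 18.0105646859
  lad <- ms2_ladders(s, "hydroxyl", "linear-phosphate", max_charge = 1)
  precursor <- monoisotopic_mass(oligo_composition(s, "hydroxyl",
                                                   "linear-phosphate"))
  n <- nchar(s)
  for (i in 1:(n - 1)) {
    ci <- lad$mass[lad$series == "c" & lad$index == i][1]
    yi <- lad$mass[lad$series == "y" & lad$index == n - i][1]
    expect_equal(ci + yi, precursor + water, tolerance = 1e-9)
    # w = y + HPO3
    wi <- lad$mass[lad$series == "w" & lad$index == n - i][1]
    expect_equal(wi - yi, 79.96633, tolerance = 1e-4)
  }
  # a methyl on residue i shifts exactly the ions containing residue i
  i <- 4
  me <- ms2_ladders(s, "hydroxyl", "linear-phosphate",
                    mods = data.frame(position = i, mod_type = "2'-O-methyl"),
                    max_charge = 1)
  delta <- me$mass - lad$mass
  contains_i <- ifelse(me$series %in% c("c", "a-B"), me$index >= i,
                       me$index > n - i)
  expect_equal(delta[contains_i], rep(14.0157, sum(contains_i)),
               tolerance = 1e-4)
  expect_equal(delta[!contains_i], rep(0, sum(!contains_i)))
  expect_error(ms2_ladders("A"), "length")
})
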