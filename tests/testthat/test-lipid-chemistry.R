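test_that("formula parsing, formatting and arithmetic behave element-wise", {
  f <- parseFormula("C59H90O4")
  expect_equal(elementCount(f, "C"), 59L)
  expect_equal(formatFormula(f), "C59H90O4")
  expect_equal(formatFormula(parseFormula("C10H6D6O4")), "C10H6D6O4")
  expect_equal(formatFormula(elementalFormula()), "(empty)")

  a <- parseFormula("C3H8O3")
  b <- parseFormula("C18H34O2")
  expect_equal((a + b)@counts, a@counts + b@counts)
  expect_equal(((a + b) - b)@counts, a@counts)
  expect_error(a - b, "negative")
  expect_equal((3 * b)@counts, 3L * b@counts)
  expect_error(parseFormula("C10X2"), "unsupported element")
  expect_error(parseFormula("c10"), "malformed|unsupported")
})

test_that("mass additivity holds over random formulas", {
  set.seed(42)
  for (i in 1:50) {
    ca <- sample(0:30, 8); cb <- sample(0:30, 8)
    names(ca) <- names(cb) <- c("C", "H", "D", "N", "O", "P", "Na", "S")
    fa <- do.call(elementalFormula, as.list(ca))
    fb <- do.call(elementalFormula, as.list(cb))
    expect_equal(monoisotopicMass(fa + fb),
                 monoisotopicMass(fa) + monoisotopicMass(fb),
                 tolerance = 1e-12)
    expect_equal(monoisotopicMass(fa), oracleMass(ca), tolerance = 1e-12)
  }
})

test_that("monoisotopic masses match independently summed values", {
  expect_equal(monoisotopicMass("C10H12O4"), 196.073559, tolerance = 5e-7)
  expect_equal(monoisotopicMass("C10H6D6O4"), 202.111219, tolerance = 5e-7)
  expect_equal(monoisotopicMass(elementalFormula()), 0)
})

test_that("adduct m/z follows the stated electron conventions", {
  # proton convention: [M+H]+ adds exactly the proton mass
  m <- monoisotopicMass("C10H12O4")
  expect_equal(adductMz("C10H12O4", "[M+H]+"), m + protonMass(),
               tolerance = 1e-9)
  # hydrogen-atom convention adds the neutral H mass (one electron heavier)
  expect_equal(adductMz("C10H12O4", adduct("[M+H]+", "hydrogen")) -
                 adductMz("C10H12O4", "[M+H]+"), electronMass(),
               tolerance = 1e-9)
  # [M+H]+ and [M-H]- differ by twice the proton mass for any neutral M
  set.seed(7)
  for (i in 1:20) {
    f <- elementalFormula(C = sample(1:40, 1), H = sample(2:60, 1),
                          O = sample(0:6, 1))
    expect_equal(adductMz(f, "[M+H]+") - adductMz(f, "[M-H]-"),
                 2 * protonMass(), tolerance = 1e-12)
  }
  expect_error(adduct("[M+X]+"), "unknown adduct")
})

test_that("lipid name parsing is structured and round-trips", {
  tg <- parseLipidName("TG 18:1/18:1/18:1")
  expect_s4_class(tg, "LipidSpecies")
  expect_length(tg@chains, 3L)
  expect_true(all(vapply(tg@chains, slot, integer(1), "carbons") == 18L))

  fa <- parseLipidName("FA18:2<OOH>")
  expect_equal(fa@lipidClass, "FA")
  expect_equal(fa@modifications@nOOH, 1L)

  corpus <- c(
    "TG 18:1/18:1/18:1", "TG 52:3", "TG 56:6<OOH>", "DG 36:2",
    "DG 18:1_18:1", "CE 20:4", "CE 18:2<2OH>", "CE 22:6<OH,oxo>",
    "PC 34:1", "PC 16:0/18:1", "PC 36:4<OOH>", "O-PC 34:2", "P-PC 36:4",
    "PE 38:4", "PE 18:0/20:4", "O-PE 36:2", "P-PE 38:5", "LPC 16:0",
    "LPC 18:1<OH>", "LPE 18:0", "PS 36:1", "PS 18:0/18:1", "PI 38:4",
    "PI 16:0/20:4", "PG 34:1", "PG 16:0/18:1", "SM 34:1", "SM 42:2",
    "Cer 34:1", "Cer 42:2", "FA16:0", "FA18:1", "FA18:2<OOH>",
    "FA20:4<OH>", "FA22:6<oxo,OOH>", "TG 16:0/18:1/20:4",
    "TG 18:0_18:1_18:2", "CE 20:4<OOH>", "PC 38:6<2OH>", "PE 40:6<oxo>",
    "O-PC 36:3", "P-PE 40:6", "LPC 20:4", "LPE 22:6", "PS 40:6",
    "PI 36:2", "PG 36:2", "SM 36:1", "Cer 40:1", "CoQ10")
  for (nm in corpus)
    expect_identical(formatLipidName(parseLipidName(nm)), nm)

  expect_error(parseLipidName("XX 34:1"), "unknown lipid class")
  expect_error(parseLipidName("TG 18:1/18:1"), "expects 3 chains")
  expect_error(parseLipidName("PC 34:x"), "malformed")
})

test_that("species formulas match known compositions", {
  expect_equal(formatFormula(speciesFormula("TG 18:1/18:1/18:1")),
               "C57H104O6")  # glycerol + 3 oleic acids - 3 waters
  expect_equal(formatFormula(speciesFormula("FA18:0")), "C18H36O2")
  expect_equal(formatFormula(speciesFormula("CoQ10")), "C59H90O4")
  expect_equal(formatFormula(speciesFormula("CoQ10-d6")), "C59H84D6O4")
  # reference compositions: PC 16:0/18:1 (POPC), CE 18:1, SM 34:1
  expect_equal(formatFormula(speciesFormula("PC 16:0/18:1")), "C42H82NO8P")
  expect_equal(formatFormula(speciesFormula("CE 18:1")), "C45H78O2")
  expect_equal(formatFormula(speciesFormula("SM 34:1")), "C39H79N2O6P")
  expect_equal(formatFormula(speciesFormula("Cer 34:1")), "C34H67NO3")
  # ether and vinyl-ether subclasses differ from the diacyl by -O+2H / -O
  expect_equal(formatFormula(speciesFormula("O-PC 34:1")), "C42H84NO7P")
  expect_equal(formatFormula(speciesFormula("P-PC 34:1")), "C42H82NO7P")
  # species-level and chain-level formulas agree
  expect_equal(speciesFormula("TG 54:3")@counts,
               speciesFormula("TG 18:1/18:1/18:1")@counts)
  # modification deltas: OH +O, OOH +2O, oxo +O-2H
  base <- speciesFormula("CE 20:4")
  expect_equal(elementCount(speciesFormula("CE 20:4<OOH>"), "O") -
                 elementCount(base, "O"), 2L)
  oxo <- speciesFormula("CE 20:4<oxo>")
  expect_equal(elementCount(oxo, "O") - elementCount(base, "O"), 1L)
  expect_equal(elementCount(oxo, "H") - elementCount(base, "H"), -2L)
  expect_error(speciesFormula(lipidSpecies("ZZ", totalCarbons = 10L,
                                           totalDoubleBonds = 0L)),
               "unsupported lipid class")
})

test_that("Kendrick mass defect is invariant across CH2 homologues", {
  ch2 <- monoisotopicMass("CH2")
  k <- kendrickMassDefect(ch2)
  expect_equal(k$kendrickMass, 14, tolerance = 1e-9)
  expect_equal(k$kendrickMassDefect, 0, tolerance = 1e-9)
  # homologous series differing by CH2 share the defect
  mz0 <- adductMz(speciesFormula("TG 52:2"), "[M+Na]+")
  for (j in 1:6) {
    mzj <- mz0 + j * ch2
    expect_equal(kendrickMassDefect(mzj)$kendrickMassDefect,
                 kendrickMassDefect(mz0)$kendrickMassDefect,
                 tolerance = 1e-9)
  }
  # TG 52:2 and TG 54:2 ammonium adducts are CH2 homologues
  d1 <- kendrickMassDefect(adductMz(speciesFormula("TG 52:2"), "[M+NH4]+"))
  d2 <- kendrickMassDefect(adductMz(speciesFormula("TG 54:2"), "[M+NH4]+"))
  expect_equal(d1$kendrickMassDefect, d2$kendrickMassDefect,
               tolerance = 1e-9)
  expect_true(all(abs(kendrickMassDefect(
    seq(100, 1000, by = 7.3))$kendrickMassDefect) <= 0.5))
  expect_error(kendrickMassDefect(-5), "positive")
})
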