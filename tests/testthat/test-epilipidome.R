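test_that("modification-set enumeration matches the brute-force oracle", {
  sets <- enumerateModificationSets()
  expect_length(sets, 7L)
  expect_setequal(vapply(sets, modSetKey, character(1)),
                  oracleModSets(2, 3, 2, 1, 1, 0))
  # the seven default sets, as shorthand
  expect_setequal(vapply(sets, formatModifications, character(1)),
                  c("<OH>", "<2OH>", "<oxo>", "<OOH>", "<OH,oxo>",
                    "<OH,OOH>", "<oxo,OOH>"))
  # tighter oxygen budget
  sets1 <- enumerateModificationSets(oxidationConstraints(maxTotalO = 1))
  expect_setequal(vapply(sets1, formatModifications, character(1)),
                  c("<OH>", "<oxo>"))
  expect_length(enumerateModificationSets(
    oxidationConstraints(0, 0, 0, 0, 0, 0)), 0L)
})

test_that("enumeration equals the oracle for 100 random constraint settings", {
  set.seed(11)
  for (i in 1:100) {
    cs <- oxidationConstraints(maxModSites = sample(0:4, 1),
                               maxTotalO = sample(0:5, 1),
                               maxOH = sample(0:3, 1),
                               maxOxo = sample(0:2, 1),
                               maxOOH = sample(0:2, 1),
                               maxEpoxy = sample(0:2, 1))
    got <- sort(vapply(enumerateModificationSets(cs), modSetKey,
                       character(1)))
    want <- oracleModSets(cs@maxModSites, cs@maxTotalO, cs@maxOH,
                          cs@maxOxo, cs@maxOOH, cs@maxEpoxy)
    expect_identical(got, want)
  }
})

test_that("relaxing any single constraint never shrinks the enumeration", {
  base <- oxidationConstraints()
  nBase <- length(enumerateModificationSets(base))
  for (slotName in c("maxModSites", "maxTotalO", "maxOH", "maxOxo",
                     "maxOOH", "maxEpoxy")) {
    relaxed <- base
    slot(relaxed, slotName) <- slot(base, slotName) + 1L
    expect_gte(length(enumerateModificationSets(relaxed)), nBase)
  }
})

test_that("oxidized-species enumeration respects eligibility and constraints", {
  expect_length(enumerateOxidizedSpecies("TG 18:0/18:0/18:0"), 0L)
  ox <- enumerateOxidizedSpecies("CE 20:4")
  expect_length(ox, 7L)
  # every output satisfies the constraint predicate (independent check)
  for (s in ox) {
    m <- s@modifications
    expect_true(m@nOH <= 2 && m@nOxo <= 1 && m@nOOH <= 1 && m@nEpoxy == 0)
    expect_lte(nModificationSites(m), 2L)
    expect_lte(addedOxygens(m), 3L)
    expect_gte(nModificationSites(m), 1L)
  }
  # no duplicate modification sets on one parent
  expect_false(anyDuplicated(vapply(ox, function(s)
    formatModifications(s@modifications), character(1))) > 0)
  expect_error(enumerateOxidizedSpecies("CE 20:4<OOH>"),
               "already oxidized")
})

test_that("target selection picks per-class top-N with correlation additions", {
  set.seed(5)
  classes <- c(TG = 25L, CE = 25L, PC = 15L)
  sim <- simulateLipidome(simulationConfig(seed = 5,
                                           featuresPerClass = classes))
  cfg <- targetSelectionConfig(topNByClass = c(TG = 20L, CE = 20L, PC = 10L))
  sel <- selectTargetLipids(sim$table, cfg)
  expect_length(sel, 50L)
  selCls <- vapply(sel, lipidClass, character(1))
  expect_equal(unname(table(selCls)[c("CE", "PC", "TG")]),
               c(20L, 10L, 20L), ignore_attr = TRUE)
  # selected TGs are exactly the 20 highest by mean intensity
  m <- assayMatrix(sim$table, "raw")
  tgs <- rownames(m)[vapply(rownames(m), lipidClass, character(1)) == "TG"]
  topTg <- tgs[order(-rowMeans(m[tgs, ]), tgs)][1:20]
  expect_setequal(sel[selCls == "TG"], topTg)

  # truncation at class size and the zero/empty edge cases
  selAll <- selectTargetLipids(sim$table,
    targetSelectionConfig(topNByClass = c(PC = 100L)))
  expect_length(selAll, 15L)
  expect_length(selectTargetLipids(sim$table,
    targetSelectionConfig(topNByClass = c(TG = 0L, CE = 0L, PC = 0L))), 0L)

  # a phenotype built from one feature's profile puts it in the
  # correlated set even at low abundance
  ph <- as.numeric(m[tgs[1], ])
  selPh <- selectTargetLipids(sim$table, targetSelectionConfig(
    topNByClass = c(CE = 5L), phenotype = ph, topNCorrelated = 3L))
  expect_true(tgs[1] %in% selPh)
})
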