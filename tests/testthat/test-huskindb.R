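test_that("readRecords parses the documented schema and converts Kp", {
  df <- rbind(toyRecord("a", -5.2), toyRecord("b", -6.8),
              toyRecord("c", -7.1))
  got <- readRecords(writeToyCsv(df))
  expect_identical(nrow(got$records), 3L)
  expect_identical(nrow(got$rejects), 0L)
  expect_equal(got$records$logkp, c(-5.2, -6.8, -7.1))
  expect_true(all(got$records$mapped))
  ## Kp supplied linearly in cm/s is log10-converted on load
  df2 <- data.frame(compound = "k", kp_cm_s = 1e-6, source = "abdomen",
                    layer = "epidermis", donor = "diluted",
                    temperature_c = 33, ph = 7.2)
  got2 <- readRecords(writeToyCsv(df2))
  expect_equal(got2$records$logkp, -6)
})

test_that("invalid rows land in the rejects report with their row number", {
  df <- rbind(toyRecord("ok", -5), toyRecord("badT", -5),
              toyRecord("noKp", NA))
  df$temperature_c[2] <- "thirty"
  path <- writeToyCsv(df)
  got <- readRecords(path)
  expect_identical(got$records$compound, "ok")
  expect_identical(sort(got$rejects$row), c(2L, 3L))
  expect_match(got$rejects$reason[got$rejects$row == 2L], "temperature")
})

test_that("missing mandatory columns are named in the error", {
  df <- data.frame(compound = "x", logkp = -5)
  expect_error(readRecords(writeToyCsv(df)), "source")
  df2 <- data.frame(compound = "x", source = "abdomen", layer = "epidermis",
                    donor = "diluted", temperature_c = 33)
  expect_error(readRecords(writeToyCsv(df2)), "logkp")
})

test_that("header matching is case-insensitive and labels are normalized", {
  df <- data.frame(Compound = "x", LogKp = -5, Source = "Abdomen",
                   Layer = "Epidermis + Dermis", Donor = "concentrated",
                   Temperature_C = 33, pH = 7.2)
  got <- readRecords(writeToyCsv(df))
  r <- got$records
  expect_identical(r$source, "abdomen")
  expect_identical(r$layer, "epidermis+dermis")
  expect_identical(r$donor, "saturated")  # neat/concentrated class
  expect_identical(r$temp_bin, "31-35")
  expect_true(r$mapped)
})

test_that("temperature bins tile the integers with nearest-integer rounding", {
  expect_identical(temperatureBin(c(20, 25, 25.4, 25.6, 30, 31, 35.4, 40)),
                   c("20-25", "20-25", "20-25", "26-30", "26-30", "31-35",
                     "31-35", "36-40"))
  expect_true(all(is.na(temperatureBin(c(19, 41, NA)))))
})

test_that("pH filtering keeps the closed interval and honours the missing-pH flag", {
  df <- rbind(toyRecord("in", -5, ph = 7.2), toyRecord("low", -5, ph = 6.5),
              toyRecord("hi", -5, ph = 7.5), toyRecord("na", -5, ph = NA))
  rec <- readRecords(writeToyCsv(df))$records
  kept <- filterPh(rec)
  expect_setequal(kept$compound, c("in", "hi", "na"))
  strict <- filterPh(rec, keepMissing = FALSE)
  expect_setequal(strict$compound, c("in", "hi"))
  expect_error(filterPh(rec, window = c(8, 7)))
})

test_that("one record per compound is selected by lexicographic preference", {
  df <- rbind(
    toyRecord("multi", -5, source = "abdomen"),
    toyRecord("multi", -9, source = "thigh"),
    toyRecord("single", -6),
    toyRecord("tied", -5), toyRecord("tied", -6))
  rec <- readRecords(writeToyCsv(df))$records
  sel <- selectOnePerCompound(rec)
  expect_identical(nrow(sel$records), 3L)
  expect_identical(sort(sel$records$compound), c("multi", "single", "tied"))
  expect_equal(sel$records$logkp[sel$records$compound == "multi"], -5)
  expect_equal(sel$records$logkp[sel$records$compound == "single"], -6)
  ## full tie: merged at the mean and logged
  expect_equal(sel$records$logkp[sel$records$compound == "tied"], -5.5)
  expect_identical(sel$ties$compound, "tied")
  expect_identical(sel$ties$n_merged, 2L)
})

test_that("layer preference outranks donor and temperature preferences", {
  df <- rbind(
    toyRecord("c1", -5, layer = "epidermis + dermis", donor = "diluted",
              temperature_c = 22),
    toyRecord("c1", -8, layer = "epidermis", donor = "saturated",
              temperature_c = 33))
  sel <- selectOnePerCompound(readRecords(writeToyCsv(df))$records)
  expect_equal(sel$records$logkp, -5)
})

test_that("compounds with excluded groups are dropped and reported", {
  df <- rbind(toyRecord("phenol", -5, smiles = "Oc1ccccc1"),
              toyRecord("fb", -6, smiles = "Fc1ccccc1"),
              toyRecord("nb", -6.5, smiles = "O=[N+]([O-])c1ccccc1"),
              toyRecord("etoh", -7, smiles = "CCO"),
              toyRecord("hexane", -7.5, smiles = "CCCCCC"))
  rec <- readRecords(writeToyCsv(df))$records
  out <- excludeUnusualCompounds(rec)
  expect_setequal(out$records$compound, c("phenol", "etoh", "hexane"))
  expect_identical(nrow(out$excluded), 2L)
  expect_setequal(out$excluded$groups, c("fluorine", "nitro"))
  ## supplied profiles take precedence over SMILES
  profs <- list(phenol = FragmentProfile(c(hydroxyl = 1),
                                         excluded = "boron"))
  out2 <- excludeUnusualCompounds(rec[rec$compound == "phenol", ], profs)
  expect_identical(nrow(out2$records), 0L)
  ## no SMILES and no profile: rejected with message
  df3 <- toyRecord("mystery", -5)
  expect_message(
    out3 <- excludeUnusualCompounds(readRecords(writeToyCsv(df3))$records),
    "mystery")
  expect_identical(out3$rejects, "mystery")
})

test_that("stratification partitions mapped records with the n > 1 rule", {
  df <- rbind(
    toyRecord(c("a", "b", "c"), c(-5, -6, -7)),                    # n = 3
    toyRecord(c("d", "e"), c(-5, -6), source = "breast"),          # n = 2
    toyRecord("f", -5, layer = "dermis"),                          # n = 1
    toyRecord("g", -5, donor = "saturated"))                       # n = 1
  rec <- readRecords(writeToyCsv(df))$records
  strat <- stratifyScenarios(rec)
  expect_length(strat$strata, 4L)
  expect_length(strat$eligible, 2L)
  sizes <- vapply(strat$strata, nrow, integer(1))
  expect_identical(sum(sizes), nrow(rec))      # partition
  expect_identical(nrow(strat$unmapped), 0L)
  ## empty input
  empty <- stratifyScenarios(rec[0, ])
  expect_length(empty$strata, 0L)
})

test_that("one record on each of the 96 keys gives 96 strata, none eligible", {
  keys <- do.call(rbind, strsplit(allScenarioKeys(), "/", fixed = TRUE))
  tempOf <- c("20-25" = 22, "26-30" = 28, "31-35" = 33, "36-40" = 38)
  df <- data.frame(compound = paste0("c", seq_len(96)), smiles = NA,
                   logkp = -6, source = keys[, 1],
                   layer = sub("_", " ", keys[, 2]), donor = keys[, 3],
                   temperature_c = unname(tempOf[keys[, 4]]), ph = 7.2,
                   reference = "toy", stringsAsFactors = FALSE)
  rec <- readRecords(writeToyCsv(df))$records
  expect_true(all(rec$mapped))
  strat <- stratifyScenarios(rec)
  expect_length(strat$strata, 96L)
  expect_length(strat$eligible, 0L)
  expect_setequal(names(strat$strata), allScenarioKeys())
})

test_that("filters are insensitive to input row order", {
  df <- rbind(toyRecord(c("a", "b", "c", "d"), c(-5, -6, -7, -8),
                        ph = c(7.2, 6.0, NA, 7.4)),
              toyRecord("a", -9, source = "thigh"))
  rec <- readRecords(writeToyCsv(df))$records
  perm <- rec[c(3, 5, 1, 4, 2), ]
  canon <- function(x) {
    out <- x[order(x$compound, x$logkp), c("compound", "logkp")]
    rownames(out) <- NULL
    out
  }
  expect_identical(canon(filterPh(rec)), canon(filterPh(perm)))
  expect_identical(canon(selectOnePerCompound(rec)$records),
                   canon(selectOnePerCompound(perm)$records))
})

test_that("outlier removal is off by default and the z-rule drops extremes", {
  df <- rbind(toyRecord(c("a", "b", "c", "x"), c(-5, -5.1, -4.9, -12)))
  rec <- readRecords(writeToyCsv(df))$records
  none <- removeOutliers(rec)
  expect_identical(nrow(none$records), 4L)
  expect_identical(nrow(none$removed), 0L)
  ## z of -12 against the stratum mean/sd is about -1.50, so tau must sit
  ## below that for the extreme record to go
  z <- removeOutliers(rec, rule = "z", tau = 1.4)
  expect_identical(sort(z$records$compound), c("a", "b", "c"))
  expect_identical(z$removed$compound, "x")
  expect_equal(z$removed$z, -1.4997, tolerance = 1e-3)
  ## all-equal stratum: sd 0 guarded, passed through untouched
  df2 <- rbind(toyRecord(c("p", "q", "r"), c(-6, -6, -6)))
  z2 <- removeOutliers(readRecords(writeToyCsv(df2))$records,
                       rule = "z", tau = 1)
  expect_identical(nrow(z2$records), 3L)
  expect_length(z2$skippedStrata, 1L)
  ## stratum of size < 3: passed through, flagged
  df3 <- rbind(toyRecord(c("s", "t"), c(-5, -9)))
  z3 <- removeOutliers(readRecords(writeToyCsv(df3))$records,
                       rule = "z", tau = 1)
  expect_identical(nrow(z3$records), 2L)
  expect_length(z3$skippedStrata, 1L)
})

test_that("the bundled fixture table exercises the full preparation chain", {
  path <- system.file("extdata", "huskindb_synthetic.csv",
                      package = "fragkin")
  got <- readRecords(path)
  expect_identical(nrow(got$records) + nrow(got$rejects), 25L)
  expect_gt(nrow(got$rejects), 0L)
  kept <- filterPh(got$records)
  sel <- selectOnePerCompound(kept)
  expect_identical(anyDuplicated(sel$records$compound), 0L)
  ok <- excludeUnusualCompounds(sel$records)
  expect_gt(nrow(ok$excluded), 0L)
  strat <- stratifyScenarios(ok$records)
  expect_gt(length(strat$eligible), 0L)
})
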