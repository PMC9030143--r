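test_that("null-effect specs give every group the identical template", {
  spec <- cohortSpec(roiCount = 8, framesPerScan = 30,
                     groups = c(NC = 2, sMCI = 2, pMCI = 2, AD = 2),
                     edgeEffect = 0, progressionRate = 0, seed = 5)
  tpl <- buildTemplates(spec)
  for (g in c("sMCI", "pMCI", "AD")) for (tp in timepointLevels())
    expect_equal(tpl$templates[[g]][[tp]], tpl$templates$NC$BL)
})

test_that("NC templates are identical across timepoints; progressive groups decline", {
  spec <- cohortSpec(roiCount = 12, framesPerScan = 30,
                     groups = c(NC = 2, sMCI = 2, pMCI = 2, AD = 2),
                     edgeEffect = 0.4, progressionRate = 0.2, seed = 6)
  tpl <- buildTemplates(spec)
  expect_equal(tpl$templates$NC$`12m`, tpl$templates$NC$BL)
  expect_equal(tpl$templates$NC$`24m`, tpl$templates$NC$BL)
  # stable MCI carries the group effect but does not progress
  expect_equal(tpl$templates$sMCI$`24m`, tpl$templates$sMCI$BL)
  aff <- tpl$affectedEdges
  meanAbs <- function(m) mean(abs(upperTriVec(m)[aff]))
  expect_lte(meanAbs(tpl$templates$AD$`24m`), meanAbs(tpl$templates$AD$BL))
  expect_lte(meanAbs(tpl$templates$AD$BL), meanAbs(tpl$templates$NC$BL))
})

test_that("templates are valid correlation matrices (symmetric, unit diagonal, PSD)", {
  spec <- cohortSpec(roiCount = 15, framesPerScan = 30,
                     groups = c(NC = 2, AD = 2), edgeEffect = 0.6,
                     progressionRate = 0.3, seed = 7)
  tpl <- buildTemplates(spec)
  for (g in names(tpl$templates)) for (tp in timepointLevels()) {
    m <- tpl$templates[[g]][[tp]]
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 15))
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("trajectory-only cohorts share baseline marginals across groups", {
  spec <- cohortSpec(roiCount = 10, framesPerScan = 30,
                     groups = c(NC = 2, AD = 2), edgeEffect = 0.5,
                     progressionRate = 0.3, trajectoryOnly = TRUE, seed = 8)
  tpl <- buildTemplates(spec)
  expect_equal(tpl$templates$AD$BL, tpl$templates$NC$BL)
  expect_false(isTRUE(all.equal(tpl$templates$AD$`24m`,
                                tpl$templates$NC$`24m`)))
})

test_that("identical seeds reproduce the cohort exactly", {
  spec <- cohortSpec(roiCount = 6, framesPerScan = 20,
                     groups = c(NC = 3, AD = 3), seed = 9)
  c1 <- simulateCohort(spec)
  c2 <- simulateCohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  for (k in names(c1$series))
    expect_identical(seriesValues(c1$series[[k]]),
                     seriesValues(c2$series[[k]]))
})

test_that("manifest covers every subject-timepoint and series match the spec size", {
  ch <- tinyCohort(groups = c(NC = 4, pMCI = 3), roiCount = 7,
                   framesPerScan = 25)
  expect_equal(nrow(ch$manifest), (4 + 3) * 3)
  expect_setequal(unique(ch$manifest$timepoint), timepointLevels())
  s1 <- ch$series[[1]]
  expect_equal(dim(seriesValues(s1)), c(25, 7))
})

test_that("sample FC converges to the generating template as scan length grows", {
  base <- cohortSpec(roiCount = 8, groups = c(NC = 20), edgeEffect = 0,
                     subjectNoiseSd = 0, seed = 10)
  dev <- function(Tn) {
    spec <- cohortSpec(roiCount = 8, framesPerScan = Tn,
                       groups = c(NC = 20), edgeEffect = 0,
                       subjectNoiseSd = 0, seed = 10)
    ch <- simulateCohort(spec)
    tplv <- upperTriVec(ch$templates$templates$NC$BL)
    devs <- vapply(names(ch$series)[grepl("BL", names(ch$series))],
                   function(k) {
                     mean(abs(upperTriVec(pearsonFC(ch$series[[k]])) - tplv))
                   }, numeric(1))
    mean(devs)
  }
  expect_lt(dev(2000), dev(100))
})

test_that("cohort writing produces a readable manifest, series files, and spec sidecar", {
  dir <- withr::local_tempdir()
  spec <- cohortSpec(roiCount = 5, framesPerScan = 15,
                     groups = c(NC = 2, AD = 2), seed = 11)
  ch <- simulateCohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "cohort_spec.json")))
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(man), 12)
  back <- readRoiSeries(man$seriesPath[1])
  expect_equal(seriesValues(back),
               seriesValues(ch$series[[paste(man$subjectId[1],
                                             man$timepoint[1], sep = ".")]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  sidecar <- jsonlite::read_json(file.path(dir, "cohort_spec.json"))
  expect_equal(sidecar$seed, 11)
})

test_that("task assembly labels the diseased group positive and keeps timepoint order", {
  ch <- tinyCohort(groups = c(NC = 3, sMCI = 3, pMCI = 3, AD = 3),
                   roiCount = 6, framesPerScan = 20)
  s <- cohortSamples(ch, "nc-ad")
  expect_length(s, 6)
  labs <- vapply(s, function(x) x@label, integer(1))
  grp <- substr(names(labs), 1, 2)
  expect_true(all(labs[grp == "AD"] == 1L))
  expect_true(all(labs[grp == "NC"] == 0L))
  expect_equal(vapply(s[[1]]@fcList, timepoint, character(1)),
               timepointLevels())
  s2 <- cohortSamples(ch, "smci-pmci")
  labs2 <- vapply(s2, function(x) x@label, integer(1))
  expect_true(all(labs2[substr(names(labs2), 1, 4) == "pMCI"] == 1L))
  expect_error(cohortSamples(tinyCohort(groups = c(NC = 2, AD = 2),
                                        roiCount = 5, framesPerScan = 15),
                             "smci-pmci"),
               "lacks group")
})
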