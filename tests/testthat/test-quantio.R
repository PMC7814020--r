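test_that("a literal dataset round-trips through the TSV writers", {
  ds <- toyDataset()
  dir <- withr::local_tempdir()
  writeSpectralCounts(ds, dir)
  back <- readSpectralCounts(file.path(dir, "counts.tsv"),
                             file.path(dir, "lengths.tsv"),
                             file.path(dir, "traits.tsv"))
  expect_identical(spcCounts(back), spcCounts(ds))
  expect_identical(proteinLengths(back), proteinLengths(ds))
  expect_identical(lesionTrait(back), lesionTrait(ds))

  # literal 3 x 2 example
  f <- file.path(dir, "c2.tsv")
  writeLines(c("protein_id\tS1\tS2", "A\t1\t0", "B\t2\t3", "C\t0\t0"), f)
  writeLines(c("protein_id\tlength_aa", "A\t10", "B\t20", "C\t30"),
             file.path(dir, "l2.tsv"))
  writeLines(c("sample_id\ttrait", "S1\thot", "S2\tCold"),
             file.path(dir, "t2.tsv"))
  ds2 <- readSpectralCounts(f, file.path(dir, "l2.tsv"),
                            file.path(dir, "t2.tsv"))
  expect_equal(dim(ds2), c(3L, 2L))
  expect_equal(unname(spcCounts(ds2)),
               matrix(c(1L, 0L, 2L, 3L, 0L, 0L), 3, byrow = TRUE))
  expect_equal(unname(lesionTrait(ds2)), c(1L, 0L))
})

test_that("run columns can be summed or averaged into samples", {
  dir <- withr::local_tempdir()
  writeLines(c("protein_id\tr1\tr2\tr3\tr4", "A\t1\t2\t3\t5"),
             file.path(dir, "c.tsv"))
  writeLines(c("protein_id\tlength_aa", "A\t10"), file.path(dir, "l.tsv"))
  writeLines(c("sample_id\ttrait", "S1\tHOT", "S2\tCOLD"),
             file.path(dir, "t.tsv"))
  rm2 <- data.frame(run = paste0("r", 1:4), sample = rep(c("S1", "S2"), 2))
  dsSum <- readSpectralCounts(file.path(dir, "c.tsv"),
                              file.path(dir, "l.tsv"),
                              file.path(dir, "t.tsv"), runMap = rm2)
  expect_equal(unname(spcCounts(dsSum)[1, ]), c(4L, 7L))
  dsMean <- readSpectralCounts(file.path(dir, "c.tsv"),
                               file.path(dir, "l.tsv"),
                               file.path(dir, "t.tsv"), runMap = rm2,
                               aggregate = "mean")
  expect_equal(unname(spcCounts(dsMean)[1, ]), c(2L, 4L))
})

test_that("validation errors name the offending record", {
  dir <- withr::local_tempdir()
  writeLines(c("protein_id\tS1\tS2", "P1\t1\t0", "P1\t2\t3"),
             file.path(dir, "c.tsv"))
  writeLines(c("protein_id\tlength_aa", "P1\t10"), file.path(dir, "l.tsv"))
  writeLines(c("sample_id\ttrait", "S1\tHOT", "S2\tCOLD"),
             file.path(dir, "t.tsv"))
  expect_error(readSpectralCounts(file.path(dir, "c.tsv"),
                                  file.path(dir, "l.tsv"),
                                  file.path(dir, "t.tsv")), "P1")

  writeLines(c("protein_id\tS1\tS2", "P1\t1\t0", "P2\t-2\t3"),
             file.path(dir, "c.tsv"))
  writeLines(c("protein_id\tlength_aa", "P1\t10", "P2\t10"),
             file.path(dir, "l.tsv"))
  expect_error(readSpectralCounts(file.path(dir, "c.tsv"),
                                  file.path(dir, "l.tsv"),
                                  file.path(dir, "t.tsv")),
               "negative")

  writeLines(c("protein_id\tS1\tS2", "P1\t1\t0", "P2\t2\t3"),
             file.path(dir, "c.tsv"))
  writeLines(c("sample_id\ttrait", "S1\tWARM", "S2\tCOLD"),
             file.path(dir, "t.tsv"))
  expect_error(readSpectralCounts(file.path(dir, "c.tsv"),
                                  file.path(dir, "l.tsv"),
                                  file.path(dir, "t.tsv")), "WARM")

  writeLines(c("sample_id\ttrait", "S1\tHOT", "S2\tCOLD"),
             file.path(dir, "t.tsv"))
  writeLines(c("protein_id\tlength_aa", "P1\t10"), file.path(dir, "l.tsv"))
  expect_error(readSpectralCounts(file.path(dir, "c.tsv"),
                                  file.path(dir, "l.tsv"),
                                  file.path(dir, "t.tsv")), "P2")
})

test_that("presence flags follow total group detection", {
  ds <- toyDataset()
  fl <- presenceFlags(ds)
  expect_equal(unname(fl[, "hot"]), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(fl[, "cold"]), c(FALSE, TRUE, TRUE, TRUE))
})

test_that("venn summary counts, percentages and rounding behave", {
  # 4 proteins: 1 HOT-only, 1 COLD-only (P2: zero in HOT), 1 COLD-only,
  # 1 common -> recompute from a crafted dataset with 2 common
  cnt <- matrix(0L, 4, 4,
                dimnames = list(paste0("P", 1:4), paste0("S", 1:4)))
  cnt[1, 1] <- 3L                  # HOT-only
  cnt[2, 3] <- 2L                  # COLD-only
  cnt[3, c(1, 3)] <- 1L            # common
  cnt[4, c(2, 4)] <- 5L            # common
  ds <- SpectralCountExperiment(cnt, setNames(rep(100, 4), rownames(cnt)),
                                setNames(c(1, 1, 0, 0), colnames(cnt)))
  v <- vennSummary(ds)
  expect_equal(v$n_total, 4)
  expect_equal(c(v$pct_hot_unique, v$pct_cold_unique, v$pct_common),
               c(25, 25, 50))
  expect_equal(v$pct_hot_unique + v$pct_cold_unique + v$pct_common, 100)

  # invariant under permutations of proteins and of samples within a group
  ds2 <- SpectralCountExperiment(cnt[c(3, 1, 4, 2), c(2, 1, 4, 3)],
                                 setNames(rep(100, 4), rownames(cnt)),
                                 setNames(c(1, 1, 0, 0), colnames(cnt)[c(2, 1, 4, 3)]))
  expect_equal(vennSummary(ds2)[c("n_hot_unique", "n_cold_unique",
                                  "n_common")],
               v[c("n_hot_unique", "n_cold_unique", "n_common")])

  # every protein in both groups
  allc <- matrix(1L, 2, 4,
                 dimnames = list(c("A", "B"), paste0("S", 1:4)))
  dsAll <- SpectralCountExperiment(allc, c(A = 10, B = 10),
                                   setNames(c(1, 1, 0, 0), paste0("S", 1:4)))
  vAll <- vennSummary(dsAll)
  expect_equal(vAll$pct_common, 100)
  expect_equal(vAll$pct_hot_unique, 0)

  expect_error(vennSummaryCounts(0, 0, 0), "no detected proteins")
})
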