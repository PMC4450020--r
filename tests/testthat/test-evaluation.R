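test_that("feature selection is the union of nonzero loadings across ranks", {
  bn <- c("A", "B")
  fn <- list(c("a1", "a2", "a3"), c("b1", "b2"))
  ls0 <- manual_loading_set(
    list(list(c(0, 0, 0), c(0, 0))), bn, fn)
  expect_true(all(!unlist(selectFeatures(ls0))))
  ls1 <- manual_loading_set(
    list(list(c(0, 1e-12, 0.3), c(0, 0))), bn, fn)
  sel <- selectFeatures(ls1)
  expect_identical(unname(which(sel$A)), c(2L, 3L))  # strict > 0
  # two ranks with disjoint support select the union
  ls2 <- manual_loading_set(
    list(list(c(1, 0, 0), c(0, 0)), list(c(0, 0, 2), c(0, 1))), bn, fn)
  sel2 <- selectFeatures(ls2)
  expect_identical(unname(which(sel2$A)), c(1L, 3L))
  expect_identical(unname(which(sel2$B)), 2L)
  # a positive threshold drops small loadings
  expect_identical(unname(which(selectFeatures(ls1, threshold = 1e-6)$A)), 3L)
})

test_that("selection scoring reproduces hand-counted confusion cells", {
  truth <- list(A = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                B = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  sel <- list(A = c(TRUE, FALSE, TRUE, FALSE, FALSE),
              B = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  sc <- scoreSelection(sel, truth)
  expect_equal(selectionConfusion(sc),
               c(TP = 2, FP = 2, TN = 5, FN = 1))
  expect_equal(selectionMetrics(sc),
               c(TPR = 2 / 3, PPV = 2 / 4, ACCU = 7 / 10))
  # pooled counts equal the sum of per-block scores
  scA <- scoreSelection(sel, truth, "A")
  scB <- scoreSelection(sel, truth, "B")
  expect_equal(selectionConfusion(sc),
               selectionConfusion(scA) + selectionConfusion(scB))
  # accuracy is invariant to block order
  sc_rev <- scoreSelection(sel[c("B", "A")], truth[c("B", "A")])
  expect_equal(selectionMetrics(sc_rev)["ACCU"], selectionMetrics(sc)["ACCU"])
})

test_that("perfect and empty selections hit the metric boundaries", {
  truth <- list(X = c(rep(TRUE, 30), rep(FALSE, 570)))
  perfect <- scoreSelection(list(X = truth$X), truth)
  expect_equal(selectionMetrics(perfect), c(TPR = 1, PPV = 1, ACCU = 1))
  empty <- scoreSelection(list(X = rep(FALSE, 600)), truth)
  m <- selectionMetrics(empty)
  expect_equal(m[["TPR"]], 0)
  expect_equal(m[["ACCU"]], 570 / 600)
  expect_equal(m[["PPV"]], 0)  # 0/0, defined as 0 and flagged
  expect_match(empty@flags, "PPV", all = FALSE)
})

test_that("selection scoring validates mask alignment", {
  truth <- list(A = c(TRUE, FALSE))
  expect_error(scoreSelection(list(A = c(TRUE, FALSE, TRUE)), truth),
               "length")
  expect_error(scoreSelection(list(B = TRUE), truth), "no selection mask")
})

test_that("a single-replication study summarizes to that replication", {
  st <- runStudy(nReplications = 1, methods = "multida", masterSeed = 5,
                 n = 60, options = fitOptions(nRanks = 1))
  expect_identical(nrow(st$summary), 3L)
  expect_equal(st$summary$sd, rep(0, 3))
  expect_equal(st$summary$mean,
               unname(unlist(st$replications[1, c("TPR", "PPV", "ACCU")])))
  expect_identical(st$nFailed, 0L)
})

test_that("studies are reproducible from the master seed", {
  s1 <- runStudy(nReplications = 2, methods = c("multida", "sgcca"),
                 masterSeed = 11, n = 60, options = fitOptions(nRanks = 1))
  s2 <- runStudy(nReplications = 2, methods = c("multida", "sgcca"),
                 masterSeed = 11, n = 60, options = fitOptions(nRanks = 1))
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$replications, s2$replications)
})

test_that("failed replications are warned about and excluded, not dropped", {
  # cvFolds larger than the sample count makes every fit fail
  wrn <- testthat::capture_warnings(
    st <- runStudy(nReplications = 2, methods = "multida", masterSeed = 3,
                   n = 40, options = fitOptions(nRanks = 1, cvFolds = 100)))
  expect_true(any(grepl("failed", wrn)))
  expect_identical(st$nFailed, 2L)
  expect_identical(nrow(st$replications), 2L)
  expect_true(all(st$replications$failed))
  expect_identical(st$summary$n_reps, rep(0L, 3))
})

test_that("study results serialize to TSV and JSON", {
  st <- runStudy(nReplications = 1, methods = "multida", masterSeed = 5,
                 n = 60, options = fitOptions(nRanks = 1))
  dir <- withr::local_tempdir()
  writeStudy(st, dir)
  tsv <- utils::read.delim(file.path(dir, "study_summary.tsv"))
  expect_equal(tsv$mean, st$summary$mean, tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(dir, "study_replications.json"),
                            simplifyVector = TRUE)
  expect_equal(js$replications$TPR, st$replications$TPR, tolerance = 1e-12)
})
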