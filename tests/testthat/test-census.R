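test_that("small-order censuses cover every isomorphism class", {
  cen <- run_census(2:5)
  expect_equal(as.integer(table(cen$order)[c("2", "3", "4", "5")]),
               c(1L, 2L, 6L, 21L))
  summ <- summarize_census(cen)
  # isothermal = regular: K2; K3, C3=K3; K4 + C4; K5 + C5
  expect_equal(summ$isothermal, c(1, 1, 2, 2))
  # every class is accounted for
  expect_equal(summ$total,
               summ$isothermal + summ$suppressor + summ$amplifier +
                 summ$SA + summ$AS + summ$SAS + summ$ASA + summ$SASA +
                 summ$other)
  expect_equal(summ$other, rep(0, 4))
})

test_that("census output is checkpointed, resumable and deterministic", {
  f1 <- tempfile(fileext = ".tsv")
  run_census(4, out = f1)
  lines <- readLines(f1)
  expect_length(lines, 7) # header + 6 graphs
  # simulate an interrupted run: keep the first three records and resume
  f2 <- tempfile(fileext = ".tsv")
  writeLines(lines[1:4], f2)
  run_census(4, out = f2, resume = TRUE)
  expect_identical(readLines(f2), lines)
})

test_that("census rows carry barcode signs with the documented semantics", {
  res <- evofix:::.census_classify(graph_ell(6, 2, 2))
  grid <- seq(0.25, 10, 0.25)
  # a global suppressor: advantage reversed below r = 1, tie at r = 1
  expect_true(all(res$signs[grid > 1] == -1))
  expect_true(all(res$signs[grid < 1] == 1))
  expect_equal(res$signs[grid == 1], 0)
  res0 <- evofix:::.census_classify(graph_cycle(6))
  expect_true(all(res0$signs == 0))
})

test_that("barcodes export one row per graph in stable order", {
  cen <- run_census(4)
  M <- barcode_export(cen)
  expect_equal(dim(M), c(6, 40))
  expect_true(all(M[cen$classification == "isothermal", ] == 0))
  Ms <- barcode_export(cen, sort = "by-pattern")
  expect_equal(sort(rownames(Ms)), sort(rownames(M)))
  f <- tempfile()
  barcode_export(cen, out = f)
  expect_equal(nrow(read.delim(f)), 6)
})

test_that("scan-only and hybrid classifications agree on order <= 5", {
  cen_scan <- run_census(2:5, method = "scan")
  cen_hyb <- run_census(2:5)
  expect_equal(cen_scan$classification, cen_hyb$classification)
  expect_equal(cen_scan$id, cen_hyb$id)
})
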