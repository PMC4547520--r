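test_that("response matrices round-trip through CSV unchanged", {
  m <- guttman_matrix(7, 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(m, f)
  m2 <- read_responses(f)
  expect_identical(unclass(m2), unclass(m))
})

test_that("a simple 3x2 file ingests as-is", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,1", "1,0", "0,0"), f)
  m <- read_responses(f)
  expect_equal(n_persons(m), 3L)
  expect_equal(n_items(m), 2L)
  expect_equal(colnames(m), c("A", "B"))
})

test_that("listwise policy drops incomplete rows with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,1", "1,", "0,0"), f)
  expect_warning(m <- read_responses(f), "1 respondent row")
  expect_equal(n_persons(m), 2L)
  expect_error(read_responses(f, missing_policy = "error"), "non-0/1")
})

test_that("malformed inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("DEBT,DEBT", "1,1", "0,1"), f)
  expect_error(read_responses(f), "duplicate")
  writeLines(c("A,B", "1,1"), f)           # only one respondent
  expect_error(read_responses(f), "2 persons")
})

test_that("tab delimiter and a leading id column are auto-detected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tA\tB", "p1\t1\t1", "p2\t1\t0", "p3\t0\t0"), f)
  m <- read_responses(f)
  expect_equal(n_items(m), 2L)
  expect_equal(colnames(m), c("A", "B"))
  expect_equal(unname(colSums(m)), c(2, 1))
})

test_that("the packaged NART tables are internally consistent", {
  fx <- load_nart_fixture()
  expect_equal(nrow(fx$all_items), 50L)
  expect_equal(nrow(fx$mini_items), 23L)
  expect_true(all(fx$mini_items$item %in% fx$all_items$item))
  # shared items agree on percent correct between the two tables
  shared <- merge(fx$mini_items, fx$all_items, by = "item")
  expect_equal(shared$pct_correct.x, shared$pct_correct.y)
  expect_equal(shared$test_order.x, shared$test_order.y)
  # mini table rows come sorted easiest to hardest
  expect_false(is.unsorted(rev(fx$mini_items$pct_correct)))
})

test_that("fixture lookups match the published item statistics", {
  fx <- load_nart_fixture()
  lab <- subset(fx$mini_items, item == "LABILE")
  expect_equal(lab$pct_correct, 14.1)
  expect_equal(lab$h_i, 0.581)
  expect_equal(lab$test_order, 49L)
  dem <- subset(fx$mini_items, item == "DEMESNE")
  expect_equal(dem$pct_correct, 22.0)
  expect_equal(dem$h_i, 0.701)
  easiest <- fx$all_items[which.max(fx$all_items$pct_correct), ]
  expect_equal(easiest$item, "ACHE")
  expect_equal(easiest$pct_correct, 99.3)
  expect_equal(fx$scale_h, 0.534)
})

test_that("reports persist losslessly with explicit empty sections", {
  f <- withr::local_tempfile(fileext = ".json")
  write_report(assemble_report(), f)
  rep <- read_report(f)
  expect_setequal(names(rep),
                  c("scales", "coefficients", "monotonicity", "iio",
                    "reliability", "regression"))
  expect_true(all(lengths(rep) == 0))

  m <- guttman_matrix(48, 23)
  full <- assemble_report(
    partition = aisp(m),
    scalability = scale_scalability(m),
    iio = backward_select_iio(m),
    reliability = ms_reliability(m),
    predictor = mini_nart_predictor())
  write_report(full, f)
  rep <- read_report(f)
  expect_length(rep$iio$retained, 23L)
  expect_equal(rep$reliability$ms, 1)
  # re-reading a re-written report reproduces the identical file
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f2)
  expect_identical(readLines(f), readLines(f2))
})
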