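test_that("item catalogue enforces its invariants", {
  expect_length(item_catalog()$items, 13L)
  expect_error(item_catalog(c("a", "a")), "unique")
  expect_error(item_catalog(c("a", "")), "non-empty")
  expect_error(item_catalog("a", 3, 3), "strictly less")
})

test_that("long-format files round-trip and are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- toy_records("P1")
  rec$score <- 0L
  write.csv(rec, path, row.names = FALSE, quote = FALSE)
  scores <- read_long(path)
  expect_equal(nrow(scores$records), 65L)
  expect_true(all(scores$records$score == 0L))

  # round trip on a 3-participant toy set: records identical
  toy <- longitudinal_scores(toy_records(c("A", "B", "C"), seed = 7))
  write_long(toy, path)
  expect_identical(read_long(path)$records, toy$records)
})

test_that("out-of-range, duplicate and malformed rows are rejected by line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,day,item,score",
               "P1,1,attention,4"), path)
  expect_error(read_long(path), "score out of range \\[0,3\\].*line 2")

  writeLines(c("participant,day,item,score",
               "P1,1,attention,1",
               "P1,1,attention,2"), path)
  expect_error(read_long(path), "duplicate.*line 3")

  writeLines(c("participant,day,item,score",
               "P1,one,attention,1"), path)
  expect_error(read_long(path), "malformed.*line 2")

  writeLines(c("participant,day,item,score",
               "P1,1,nonsense,1"), path)
  expect_error(read_long(path), "unknown item")
})

test_that("to_wide builds the items-by-days matrix in day-major order", {
  scores <- longitudinal_scores(toy_records(c("A", "B"), seed = 3))
  X <- to_wide(scores)
  expect_identical(dim(X), c(2L, 65L))
  expect_identical(colnames(X)[1:13], paste0(drs_r98_items(), "@d1"))

  cat1 <- item_catalog("pain", 0, 3)
  rec <- data.frame(participant = c("A", "B"), day = 1L, item = "pain",
                    score = c(0L, 3L))
  X1 <- to_wide(longitudinal_scores(rec, cat1, n_days = 1L))
  expect_equal(unname(X1), matrix(c(0, 3), 2, 1))
})

test_that("wide -> long -> wide is the identity on complete data", {
  scores <- longitudinal_scores(toy_records(c("A", "B", "C", "D"), seed = 9))
  X <- to_wide(scores)
  expect_identical(to_wide(wide_to_long(X)), X)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_wide(X, path)
  expect_equal(read_wide(path), X)
})

test_that("incomplete participants are a hard error naming the holes", {
  rec <- toy_records("A")
  rec <- rec[-1L, ]  # knock out one cell
  scores <- longitudinal_scores(rec)
  expect_false(unname(complete_participants(scores)))
  expect_error(to_wide(scores), "missing cell.*A:")
})

test_that("peak daily total severity matches direct summation", {
  items <- drs_r98_items()
  rec <- toy_records("A")
  rec$score <- 0L
  expect_equal(unname(max_total_severity(longitudinal_scores(rec), "A")), 0)

  rec$score <- ifelse(rec$day == 2, 3L, 0L)
  expect_equal(unname(max_total_severity(longitudinal_scores(rec), "A")), 39)

  rec$score <- ifelse(rec$day == 1, 1L, ifelse(rec$day == 3, 2L, 0L))
  expect_equal(unname(max_total_severity(longitudinal_scores(rec), "A")), 26)

  # invariant to record ordering, bounded by items x score_max
  shuffled <- rec[sample.int(nrow(rec)), ]
  expect_equal(max_total_severity(longitudinal_scores(shuffled), "A"),
               max_total_severity(longitudinal_scores(rec), "A"))
  expect_lte(max(max_total_severity(longitudinal_scores(rec))),
             length(items) * 3)
  expect_error(max_total_severity(longitudinal_scores(rec), "nobody"),
               "unknown participant")
})

test_that("empty record sets write header-only files", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- longitudinal_scores(toy_records(character(0)))
  write_long(empty, path)
  expect_identical(readLines(path), "participant,day,item,score")
})
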