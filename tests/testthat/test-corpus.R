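test_that("the lexicon has 60 entries in list order with valid metadata", {
  expect_equal(nrow(LEX), 60)
  expect_identical(LEX$word_id, 1:60)
  expect_equal(LEX$form[19], "casa")
  expect_equal(LEX$form[33], "de repente")
  expect_true(all(c("por isso", "a gente", "de repente", "em cima") %in%
                  LEX$form[LEX$multiword]))
  expect_true(all(LEX$stress >= 1 & LEX$stress <= LEX$n_syllables))
  spans <- attr(LEX, "syllable_spans")
  for (i in 1:60) {
    u <- segment_graphemes(LEX$form[i])$units
    expect_equal(length(spans[[i]]), length(u))
    expect_identical(sort(unique(spans[[i]])), seq_len(LEX$n_syllables[i]))
  }
})

test_that("the shipped lexicon resource matches the embedded constant", {
  path <- system.file("extdata", "dsw_lexicon.csv", package = "semiospell")
  expect_true(nzchar(path))
  onfile <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  expect_equal(onfile$form, LEX$form)
  expect_equal(onfile$syllab, LEX$syllab)
  expect_equal(onfile$stress, LEX$stress)
})

test_that("the gold fixture is well-formed and anchored in the lexicon", {
  expect_gte(nrow(GOLD), 120)
  expect_true(all(GOLD$word_id %in% LEX$word_id))
  tgt <- LEX$form[GOLD$word_id]
  norm <- vapply(GOLD$form, normalize_form, character(1), USE.NAMES = FALSE)
  expect_true(all(norm != tgt))
  expect_true(all(lengths(GOLD$labels) > 0))
  expect_true(any(GOLD$ambiguous))
  # spot checks
  hit <- GOLD$word_id == 23 & GOLD$form == "porisso" & GOLD$source == "tab1"
  expect_identical(GOLD$labels[hit][[1]], "USW")
  hit <- GOLD$word_id == 41 & GOLD$form == "girrafa"
  expect_identical(GOLD$labels[hit][[1]], "IPG_1")
})

test_that("per-word counts cover 60 words with 30 students per group", {
  expect_equal(nrow(T3), 60)
  expect_true(all(T3$gd_correct + T3$gd_incorrect == 30))
  expect_true(all(T3$gwd_correct + T3$gwd_incorrect == 30))
  expect_equal(T3[T3$form == "quando", c("gd_correct", "gd_incorrect")],
               data.frame(gd_correct = 24L, gd_incorrect = 6L, row.names = 2L))
  expect_equal(T3$gd_incorrect[T3$form == "casa"], 0L)
})

test_that("response tables round-trip and collect row-level errors", {
  df <- data.frame(student_id = c("s1", "s2", "s3", "s4"),
                   group = c("GD", "GWD", "XX", "GD"),
                   grade = c(3L, 6L, 4L, 7L),
                   word_id = c(19L, 33L, 1L, 2L),
                   written_form = c("casa", "derepente", "muito", "quando"),
                   stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".csv")
  write_responses(df, p)
  back <- read_responses(p)
  expect_equal(nrow(back), 2)              # bad group + bad grade rejected
  errs <- attr(back, "errors")
  expect_equal(nrow(errs), 2)
  expect_setequal(errs$reason, c("bad group", "bad grade"))
  # read-write-read identity on the valid subset
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(back, p2)
  again <- read_responses(p2)
  attr(again, "errors") <- NULL
  cmp <- back
  attr(cmp, "errors") <- NULL
  expect_equal(again, cmp)
  # missing column
  writeLines("student_id,group,grade", p2)
  expect_error(read_responses(p2), "missing column")
})

test_that("fixture export writes inspectable delimited copies", {
  d <- withr::local_tempdir()
  paths <- export_fixtures(d)
  expect_true(all(file.exists(file.path(d, c("dsw_lexicon.csv",
                                             "gold_fixture.csv",
                                             "table3_counts.csv",
                                             "grade_totals.csv")))))
  g <- utils::read.csv(file.path(d, "gold_fixture.csv"), encoding = "UTF-8")
  expect_equal(nrow(g), nrow(GOLD))
})
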