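test_that("classify follows the decision cascade on the canonical examples", {
  expect_true("USW" %in% predicted_for(33, "derepente"))
  expect_true("IPG_2" %in% predicted_for(53, "isami"))
  expect_identical(predicted_for(50, "arvore"), "AAW")
  cl <- classify_spelling("casa", "casa", lexicon = LEX)
  expect_equal(cl$verdict, "correct")
  expect_equal(nrow(cl$labels), 0)
  expect_true(all(c("OIL", "IPG_1") %in% predicted_for(7, "cosegiu")))
})

test_that("substitutions are labeled by the precedent table", {
  lab <- function(t, w) classify_spelling(t, w, lexicon = LEX)$labels
  l <- lab("tempo", "tenpo")
  expect_equal(l$category, "IPG_1")
  l <- lab("homem", "homen")
  expect_equal(l$category, "IPG_2")
  l <- lab("de repente", "te repente")
  expect_true("RPG" %in% l$category)
  l <- lab("disse", "dice")
  expect_equal(l$category, "IPG_1")
})

test_that("indels are labeled by the doubled-digraph and silent-h precedents", {
  expect_identical(predicted_for(10, "guera"), "IPG_1")     # rr -> r
  expect_identical(predicted_for(21, "omem"), "IPG_2")      # silent h dropped
  expect_identical(predicted_for(1, "muinto"), "OIL")       # plain insertion
})

test_that("the OTHER gate catches non-letters, low similarity and listed forms", {
  expect_true(is_other_form("tenho", "temum", lexicon = LEX))
  expect_true(is_other_form("futebol", "futball", lexicon = LEX))
  expect_false(is_other_form("casa", "casa", lexicon = LEX))
  expect_true(is_other_form("casa", "x7!", lexicon = LEX))
  cl <- classify_spelling("almoço", "almoção", lexicon = LEX)
  expect_equal(cl$verdict, "other")
  expect_equal(cl$labels$category, "OTHER")
})

test_that("classification is deterministic and OTHER is exclusive", {
  a <- classify_spelling(7, "cosegiu", lexicon = LEX)
  b <- classify_spelling(7, "cosegiu", lexicon = LEX)
  expect_identical(a$labels, b$labels)
  for (k in which(GOLD$form %in% c("temum", "futball", "almoção"))) {
    cl <- classify_spelling(GOLD$word_id[k], GOLD$form[k], lexicon = LEX)
    expect_equal(cl$verdict, "other")
    expect_identical(unique(cl$labels$category), "OTHER")
  }
})

test_that("every emitted label respects the natural/arbitrary partition", {
  for (k in seq_len(nrow(GOLD))) {
    cl <- classify_spelling(GOLD$word_id[k], GOLD$form[k], lexicon = LEX)
    l <- cl$labels
    expect_true(all(l$spelling_class[l$category %in% c("RPG", "OIL", "ASS", "USW")]
                    == "natural"))
    expect_true(all(l$spelling_class[l$category %in% c("IPG_1", "IPG_2", "AAW")]
                    == "arbitrary"))
    expect_true(all(l$spelling_class[l$category == "OTHER"] == "other"))
  }
})

test_that("taxonomy-table examples are all contained in the predicted label sets", {
  t1 <- GOLD[GOLD$source == "tab1", ]
  for (k in seq_len(nrow(t1))) {
    pred <- predicted_for(t1$word_id[k], t1$form[k])
    expect_true(all(t1$labels[[k]] %in% pred),
                info = sprintf("%s: want %s got %s", t1$form[k],
                               paste(t1$labels[[k]], collapse = "+"),
                               paste(pred, collapse = "+")))
  }
})

test_that("at least 90% of unambiguous per-word-analysis labels are recovered", {
  s41 <- GOLD[GOLD$source == "s41" & !GOLD$ambiguous, ]
  tot <- 0L; hit <- 0L
  for (k in seq_len(nrow(s41))) {
    pred <- predicted_for(s41$word_id[k], s41$form[k])
    tot <- tot + length(s41$labels[[k]])
    hit <- hit + sum(s41$labels[[k]] %in% pred)
  }
  expect_gte(tot, 100)
  expect_gte(hit / tot, 0.90)
})
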