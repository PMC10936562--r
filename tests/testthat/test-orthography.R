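test_that("normalization lowercases, trims, collapses whitespace and composes NFC", {
  expect_equal(normalize_form("Derepente "), "derepente")
  expect_equal(normalize_form("em  baixo"), "em baixo")
  decomposed <- paste0("a", "́", "rvore")  # a + combining acute
  expect_equal(normalize_form(decomposed), "árvore")
  expect_equal(normalize_form(normalize_form(decomposed)), "árvore")
  expect_error(normalize_form("   "), "blank")
})

test_that("grapheme segmentation munches digraphs maximally and records boundaries", {
  expect_equal(segment_graphemes("cachorro")$units, c("c", "a", "ch", "o", "rr", "o"))
  expect_equal(segment_graphemes("guerra")$units, c("gu", "e", "rr", "a"))
  gs <- segment_graphemes("por isso")
  expect_equal(gs$units, c("p", "o", "r", "i", "ss", "o"))
  expect_equal(gs$boundaries, 3L)
  # qu/gu are digraphs only before a vowel; sc only before e/i
  expect_equal(segment_graphemes("aguda")$units, c("a", "g", "u", "d", "a"))
  expect_equal(segment_graphemes("escola")$units, c("e", "s", "c", "o", "l", "a"))
  expect_error(segment_graphemes("ab3"), "non_alphabetic")
})

test_that("segmentation round-trips: joining units reproduces the form", {
  set.seed(101)
  for (k in 1:200) {
    form <- random_form(sample(2:12, 1))
    gs <- segment_graphemes(form)
    expect_equal(paste(gs$units, collapse = ""), form)
  }
  for (w in LEX$form) {
    gs <- segment_graphemes(w)
    u <- gs$units
    for (b in rev(gs$boundaries)) u <- append(u, " ", after = b)
    expect_equal(paste(u, collapse = ""), w)
  }
})

test_that("g2p applies the reading-direction rule table", {
  expect_equal(unclass(g2p("casa")), c("k", "a", "z", "a"))
  expect_equal(unclass(g2p("gente"))[1], "Z")
  p <- unclass(g2p("vez"))
  expect_equal(p[length(p)], "S")
  # determinism
  expect_identical(g2p("conseguiu"), g2p("conseguiu"))
  # silent h, nasal coda, final raising
  expect_equal(unclass(g2p("homem")), c("o", "m", "e", "N"))
  expect_equal(unclass(g2p("tempo")), c("t", "e", "N", "p", "u"))
})

test_that("every non-silent grapheme unit contributes at least one phoneme", {
  for (i in 1:60) {
    meta <- dsw_entry(i, LEX)
    toks <- semiospell:::split_tokens(segment_graphemes(meta$form))
    x_sound <- if (isTRUE(meta$x_reads_z)) "z" else NULL
    for (tok in toks) {
      for (j in seq_along(tok)) {
        ph <- semiospell:::unit_phones(tok, j, x_sound)
        if (tok[j] == "h") {
          expect_length(ph, 0)
        } else {
          expect_gte(length(ph), 1)
        }
      }
    }
  }
})

test_that("phonological equivalence follows the per-word reading judgments", {
  expect_true(phonologically_equivalent("a gente", "agenti",
                                        dsw_entry("a gente", LEX)))
  expect_false(phonologically_equivalent("começou", "comeco",
                                         dsw_entry("começou", LEX)))
  # reflexive and symmetric
  set.seed(7)
  forms <- sample(LEX$form, 12)
  for (f in forms) {
    expect_true(phonologically_equivalent(f, f))
  }
  expect_equal(phonologically_equivalent("casa", "caza"),
               phonologically_equivalent("caza", "casa"))
  expect_true(phonologically_equivalent("casa", "caza"))
})

test_that("rule lookup returns matching slot rules ordered by specificity", {
  r <- lookup_rules("tempo", 3, dsw_entry("tempo", LEX))
  expect_true("nasal-before-p/b" %in% r$rule_id)
  expect_equal(r$rule_class[1], "contextual")
  r <- lookup_rules("caiu", 4, dsw_entry("caiu", LEX))
  expect_equal(r$rule_id[1], "past-tense-semivowel")
  expect_equal(r$rule_class[1], "morphological")
  r <- lookup_rules("jeito", 1, dsw_entry("jeito", LEX))
  expect_true("g/j-before-e,i" %in% r$rule_id)
  expect_true(all(r$rule_class == "lexical"))
})
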