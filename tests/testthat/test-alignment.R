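test_that("alignment recovers the expected edit scripts", {
  s <- align_graphemes("conseguiu", "cosegiu", dsw_entry("conseguiu", LEX))
  kinds <- s$kind[s$kind != "match"]
  expect_setequal(kinds, c("deletion", "substitution"))
  expect_equal(s$t_sur[s$kind == "deletion"], "n")
  expect_equal(s$t_sur[s$kind == "substitution"], "gu")
  expect_equal(s$r_sur[s$kind == "substitution"], "g")

  s <- align_graphemes("embaixo", "ebaixo")
  expect_equal(sum(s$kind == "deletion"), 1)
  expect_equal(s$t_sur[s$kind == "deletion"], "m")
  expect_true(all(s$kind[s$kind != "deletion"] == "match"))

  s <- align_graphemes("porque", "proque")
  expect_equal(sum(s$kind == "transposition"), 1)
  expect_equal(attr(s, "cost"), 1)
})

test_that("boundary diff detects hypo- and hypersegmentation", {
  expect_equal(boundary_diff("de repente", "derepente")$kind, "join")
  expect_equal(boundary_diff("embaixo", "em baixo")$kind, "split")
  expect_equal(nrow(boundary_diff("casa", "casa")), 0)
  bd <- boundary_diff("a gente", "aje te")
  expect_setequal(bd$kind, c("join", "split"))
})

test_that("similarity is 1 on identity, fails the OTHER gate for listed forms", {
  expect_equal(grapheme_similarity("casa", "casa"), 1)
  expect_lt(grapheme_similarity("tenho", "temum", dsw_entry("tenho", LEX)), 0.5)
  expect_gte(grapheme_similarity("almoço", "almoção", dsw_entry("almoço", LEX)), 0.5)
})

test_that("applying a script to the target reproduces the response (all gold pairs)", {
  for (k in seq_len(nrow(GOLD))) {
    form <- GOLD$form[k]
    cl <- tryCatch(normalize_form(form), error = function(e) NULL)
    if (is.null(cl)) next
    meta <- dsw_entry(GOLD$word_id[k], LEX)
    rgs <- segment_graphemes(cl)
    s <- align_graphemes(segment_graphemes(meta$form), rgs, meta)
    expect_equal(apply_edit_script(s), rgs$units,
                 info = paste(meta$form, "->", form))
  }
})

test_that("alignment cost matches the no-transposition DP oracle minus transposition savings", {
  for (k in seq_len(nrow(GOLD))) {
    meta <- dsw_entry(GOLD$word_id[k], LEX)
    s <- align_graphemes(meta$form, GOLD$form[k], meta)
    oc <- oracle_dp_cost(meta$form, GOLD$form[k], meta)
    ntrans <- sum(s$kind == "transposition")
    if (ntrans == 0) {
      expect_equal(attr(s, "cost"), oc, info = GOLD$form[k])
    } else {
      # each admissible transposition saves at most 1 relative to the
      # transposition-free oracle, and never increases the cost
      expect_lte(attr(s, "cost"), oc)
      expect_gte(attr(s, "cost"), oc - ntrans)
    }
  }
})

test_that("edit ops account for both strings' lengths", {
  for (k in seq_len(nrow(GOLD))) {
    meta <- dsw_entry(GOLD$word_id[k], LEX)
    tgs <- segment_graphemes(meta$form)
    rgs <- segment_graphemes(normalize_form(GOLD$form[k]))
    s <- align_graphemes(tgs, rgs, meta)
    n_match <- sum(s$kind == "match")
    n_sub <- sum(s$kind == "substitution")
    n_del <- sum(s$kind == "deletion")
    n_ins <- sum(s$kind == "insertion")
    n_tr <- sum(s$kind == "transposition")
    expect_equal(length(tgs$units), n_match + n_sub + n_del + 2 * n_tr)
    expect_equal(length(rgs$units), n_match + n_sub + n_ins + 2 * n_tr)
  }
})
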