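test_that("the default profile encodes the study design", {
  prof <- default_profile(seed = 3)
  expect_equal(prof$groups$GD$word_error_rate, 0.4716)
  expect_equal(prof$groups$GWD$word_error_rate, 0.0716)
  expect_equal(prof$grades$n_students[prof$grades$group == "GD"],
               c(10L, 8L, 4L, 8L))
  for (g in names(prof$groups)) {
    expect_equal(sum(prof$groups[[g]]$category_mix), 1)
    expect_true(all(prof$groups[[g]]$category_mix >= 0))
  }
  mix <- prof$groups$GD$category_mix
  expect_true(mix[["IPG_1"]] > mix[["IPG_2"]] &&
              mix[["IPG_2"]] > mix[["OIL"]] &&
              mix[["OIL"]] > mix[["RPG"]] &&
              mix[["RPG"]] > mix[["ASS"]])
})

test_that("corruption operators produce the canonical category-consistent forms", {
  set.seed(9)
  usw <- replicate(5, corrupt_form("embaixo", "USW", LEX))
  expect_true("em baixo" %in% usw)
  expect_equal(unique(replicate(5, corrupt_form("árvore", "AAW", LEX))),
               "arvore")
  ipg1 <- unique(replicate(30, corrupt_form("cachorro", "IPG_1", LEX)))
  expect_true("cachoro" %in% ipg1)
  expect_true(all(vapply(ipg1, function(f) f != "cachorro", logical(1))))
  # inapplicable category signals an applicability error
  expect_error(corrupt_form("casa", "AAW", LEX), class = "applicability_error")
  expect_error(corrupt_form("casa", "OTHER", LEX), class = "applicability_error")
})

test_that("a zero-rate profile emits only correct forms, and seeds reproduce corpora", {
  prof <- default_profile(seed = 21)
  prof$groups$GD$word_error_rate <- 0
  prof$groups$GWD$word_error_rate <- 0
  sim <- simulate_dataset(prof, LEX)
  expect_equal(nrow(sim), 60 * 60)
  expect_true(all(sim$written_form == LEX$form[sim$word_id]))
  expect_true(all(sim$injected == ""))

  prof2 <- default_profile(seed = 77)
  a <- simulate_dataset(prof2, LEX)
  b <- simulate_dataset(default_profile(seed = 77), LEX)
  expect_identical(a, b)
  c2 <- simulate_dataset(default_profile(seed = 78), LEX)
  expect_false(identical(a, c2))
})

test_that("single-operator corruptions are recovered by the classifier", {
  set.seed(14)
  cats <- c("OIL", "USW", "AAW", "RPG")
  n <- 0L; ok <- 0L
  while (n < 150L) {
    ci <- sample(cats, 1)
    meta <- dsw_entry(sample.int(60, 1), LEX)
    form <- tryCatch(corrupt_form(meta, ci, LEX), error = function(e) NULL)
    if (is.null(form)) next
    n <- n + 1L
    if (ci %in% predicted_for(meta$word_id, form)) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.95)
})
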