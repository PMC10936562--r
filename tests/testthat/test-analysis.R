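test_that("word contingency tables are built from counts or classified data", {
  t <- word_contingency(T3, 2)
  expect_equal(unname(t), matrix(c(24L, 30L, 6L, 0L), 2))
  toy <- data.frame(group = rep(c("GD", "GWD"), each = 2),
                    word_id = 1L, verdict = "correct",
                    stringsAsFactors = FALSE)
  expect_equal(unname(word_contingency(toy, 1)),
               matrix(c(2L, 2L, 0L, 0L), 2))
  toy1 <- data.frame(group = c("GD", "GWD"), word_id = 1L,
                     verdict = c("misspelled", "correct"))
  t1 <- word_contingency(toy1, 1)
  expect_equal(sum(t1), 2)
  expect_error(word_contingency(toy1[1, ], 1), "both groups")
})

test_that("test selection follows the 20% expected-frequency rule", {
  expect_equal(select_test(matrix(c(24, 30, 6, 0), 2)), "fisher_exact")
  expect_equal(select_test(matrix(c(20, 25, 10, 5), 2)), "chi_square")
  expect_equal(select_test(matrix(c(15, 15, 15, 15), 2)), "chi_square")
  # never chi-square when >20% of expected cells are under 5 (all 60 tables)
  for (id in 1:60) {
    t <- word_contingency(T3, id)
    expected <- outer(rowSums(t), colSums(t)) / sum(t)
    if (mean(expected < 5) > 0.2) {
      expect_equal(select_test(t), "fisher_exact")
    }
  }
})

test_that("Fisher p matches closed-form and boundary cases", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1,
               tolerance = 1e-9)  # 2 / C(6,3)
})

test_that("Fisher p equals the exhaustive enumeration oracle and is margin-symmetric", {
  # exhaustive over all tables with N <= 15
  for (N in 2:15) {
    for (r1 in 1:(N - 1)) {
      for (c1 in 1:(N - 1)) {
        a_min <- max(0, r1 + c1 - N); a_max <- min(r1, c1)
        for (a in a_min:a_max) {
          t <- matrix(c(a, c1 - a, r1 - a, N - r1 - c1 + a), 2)
          expect_equal(fisher_exact_2x2(t)$p_value, oracle_fisher_p(t),
                       tolerance = 1e-9,
                       info = paste(c(t), collapse = ","))
        }
      }
    }
  }
  # row/column swap invariance on random larger tables
  set.seed(12)
  for (k in 1:50) {
    t <- matrix(rpois(4, 8), 2)
    if (sum(t) == 0) next
    p <- fisher_exact_2x2(t)$p_value
    expect_equal(fisher_exact_2x2(t[2:1, ])$p_value, p, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t[, 2:1])$p_value, p, tolerance = 1e-9)
  }
})

test_that("chi-square is Pearson without continuity correction", {
  r <- chi_square_2x2(matrix(c(15, 15, 15, 15), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- chi_square_2x2(matrix(c(20, 25, 10, 5), 2))
  expect_equal(r$statistic, 60 * (20 * 5 - 10 * 25)^2 / (30 * 30 * 45 * 15),
               tolerance = 1e-9)
  expect_equal(r$p_value, 0.1360, tolerance = 1e-3)
  # doubling all cells doubles the statistic
  r2 <- chi_square_2x2(2 * matrix(c(20, 25, 10, 5), 2))
  expect_equal(r2$statistic, 2 * r$statistic, tolerance = 1e-9)
  expect_warning(chi_square_2x2(matrix(c(24, 30, 6, 0), 2)), "Fisher")
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 3), 2)), "zero margin")
})

test_that("Mann-Whitney uses the exact small-sample path and matches enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1, tolerance = 1e-9)
  expect_match(r$applicability_note, "exact")
  # enumeration oracle over random untied samples, n1, n2 <= 6
  set.seed(33)
  for (k in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    xs <- sample(1:100, n1); ys <- sample(setdiff(1:100, xs), n2)
    expect_equal(mann_whitney(xs, ys)$p_value, oracle_mw_p(xs, ys),
                 tolerance = 1e-9)
  }
  # identical samples -> approximate path, p = 1
  r <- mann_whitney(rep(1:5, 3), rep(1:5, 3))
  expect_equal(r$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("normality test behaves on normal, bimodal and degenerate samples", {
  set.seed(5)
  expect_gt(ks_normality(rnorm(200))$p_value, 0.05)
  expect_lt(ks_normality(c(rep(0, 20), rep(100, 20)) + rnorm(40, 0, 0.01))$p_value,
            0.01)
  expect_error(ks_normality(c(1, 2, 3)), "n >= 4")
  expect_error(ks_normality(rep(2, 10)), "degenerate")
  expect_equal(ks_normality(rnorm(50), variant = "ks")$applicability_note,
               "plain KS, estimated parameters")
})

test_that("grade summaries reproduce means and shares from totals", {
  gs <- grade_summaries(grade_totals())
  gd3 <- gs[gs$grade == 3 & gs$group == "GD", ]
  expect_equal(gd3$mean_incorrect, 38.7)
  expect_equal(gd3$share_of_grade_errors, 86.19)
  gd6 <- gs[gs$grade == 6 & gs$group == "GD", ]
  expect_equal(gd6$share_of_grade_errors, 93.01)
  # shares within each grade sum to 100
  for (g in unique(gs$grade)) {
    expect_equal(sum(gs$share_of_grade_errors[gs$grade == g]), 100,
                 tolerance = 0.011)
  }
  single <- data.frame(grade = 3, group = "GD", n_students = 5,
                       total_incorrect = 40)
  expect_equal(grade_summaries(single)$share_of_grade_errors, 100)
  expect_error(grade_summaries(data.frame(grade = 3, group = "GD",
                                          n_students = 0,
                                          total_incorrect = 1)),
               "zero denominators")
})

test_that("distinct-form category counts deduplicate forms and split by class", {
  mk <- function(student, group, word, form, verdict, cat) {
    data.frame(student_id = student, group = group, grade = 3L, word_id = word,
               written_form = form, normalized = form, verdict = verdict,
               category = cat, spelling_class = spelling_class(cat),
               locus = "", rationale = "", notation = "",
               stringsAsFactors = FALSE)
  }
  # two students, same group, same wrong form -> one distinct form
  d <- rbind(mk("a", "GD", 1, "muinto", "misspelled", "OIL"),
             mk("b", "GD", 1, "muinto", "misspelled", "OIL"))
  out <- distinct_form_counts(d)
  expect_equal(out$OIL[out$group == "GD"], 1)
  # a form with two labels increments both categories
  d <- rbind(mk("a", "GD", 7, "cosegiu", "misspelled", "OIL"),
             mk("a", "GD", 7, "cosegiu", "misspelled", "IPG_1"))
  out <- distinct_form_counts(d)
  expect_equal(out$OIL[out$group == "GD"], 1)
  expect_equal(out$IPG_1[out$group == "GD"], 1)
  ct <- attr(out, "class_totals")
  expect_equal(ct$total, ct$natural + ct$arbitrary + ct$other)
  # empty dataset -> all zeros
  out <- distinct_form_counts(mk("a", "GD", 19, "casa", "correct", "-")[0, ])
  expect_true(all(out[, -1] == 0))
})

test_that("the list percentage uses the truncation convention", {
  expect_equal(pct_of_list(28.3), 47.16)
  expect_equal(pct_of_list(4.3), 7.16)
})
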