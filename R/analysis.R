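# Aggregation and the group-comparison statistical layer: per-word 2x2
# contingency tables, the chi-square/Fisher selection rule, Mann-Whitney,
# Lilliefors normality, per-grade summaries and distinct-form category
# counts.

new_test_result <- function(test_name, statistic, p_value, note = "") {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, applicability_note = note),
            class = "dsw_test_result")
}

#' @export
print.dsw_test_result <- function(x, ...) {
  cat(sprintf("<%s> %sp = %.4g%s\n", x$test_name,
              if (is.na(x$statistic)) "" else sprintf("stat = %.4g, ", x$statistic),
              x$p_value,
              if (nzchar(x$applicability_note)) paste0(" (", x$applicability_note, ")")
              else ""))
  invisible(x)
}

as_table2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2L, 2L)) || any(t < 0) || any(t != round(t))) {
    stop("need a 2x2 table of non-negative integer counts")
  }
  storage.mode(t) <- "integer"
  if (sum(t) == 0L) stop("zero grand total")
  t
}

#' Per-word 2x2 contingency table
#'
#' Rows are groups GD/GWD, columns correct/incorrect. With a counts table
#' (from [table3_counts()] or in the same shape) the cells are read off; with
#' a classified response table a response counts as incorrect iff its verdict
#' is not `correct`.
#'
#' @param data A counts data frame (columns `gd_correct`, `gd_incorrect`,
#'   `gwd_correct`, `gwd_incorrect`) or a classified response table with
#'   columns `group`, `word_id`, `verdict` (one row per response).
#' @param word_id Target word id.
#' @return 2x2 integer matrix with dimnames.
#' @examples
#' word_contingency(table3_counts(), 2)
#' @export
word_contingency <- function(data, word_id) {
  if (all(c("gd_correct", "gd_incorrect") %in% names(data))) {
    row <- data[data$word_id == word_id, , drop = FALSE]
    if (nrow(row) != 1L) stop("word_id not found in counts table")
    t <- matrix(c(row$gd_correct, row$gwd_correct,
                  row$gd_incorrect, row$gwd_incorrect), 2L, 2L)
  } else {
    sub <- data[data$word_id == word_id, , drop = FALSE]
    if ("student_id" %in% names(sub)) {
      sub <- unique(sub[, c("student_id", "group", "word_id", "verdict")])
    }
    if (!all(c("GD", "GWD") %in% sub$group)) {
      stop("dataset must cover both groups for the word")
    }
    inc <- sub$verdict != "correct"
    t <- matrix(c(sum(sub$group == "GD" & !inc), sum(sub$group == "GWD" & !inc),
                  sum(sub$group == "GD" & inc), sum(sub$group == "GWD" & inc)),
                2L, 2L)
  }
  dimnames(t) <- list(group = c("GD", "GWD"), result = c("correct", "incorrect"))
  as_table2x2(t)
}

#' Test selection for a 2x2 table
#'
#' The chi-square test is not applicable when more than 20% of cells have an
#' expected frequency below 5; the Fisher exact test is used instead.
#'
#' @param t 2x2 count matrix.
#' @return `"chi_square"` or `"fisher_exact"`.
#' @examples
#' select_test(matrix(c(24, 30, 6, 0), 2))
#' select_test(matrix(c(20, 25, 10, 5), 2))
#' @export
select_test <- function(t) {
  t <- as_table2x2(t)
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (mean(expected < 5) > 0.2) "fisher_exact" else "chi_square"
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass method: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' the observed table's.
#'
#' @param t 2x2 count matrix.
#' @return A `dsw_test_result` (no statistic).
#' @examples
#' fisher_exact_2x2(matrix(c(24, 30, 6, 0), 2))
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as_table2x2(t)
  p <- stats::fisher.test(t)$p.value
  new_test_result("fisher_exact", NA_real_, min(1, p))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default (switchable), 1 degree of
#' freedom, upper-tail p. Warns when the expected-frequency condition would
#' have routed the table to Fisher.
#'
#' @param t 2x2 count matrix.
#' @param yates Apply the continuity correction.
#' @return A `dsw_test_result`.
#' @export
chi_square_2x2 <- function(t, yates = FALSE) {
  t <- as_table2x2(t)
  if (any(rowSums(t) == 0L) || any(colSums(t) == 0L)) stop("zero margin")
  note <- ""
  if (select_test(t) != "chi_square") {
    warning("expected frequencies below 5 in >20% of cells; Fisher advised")
    note <- "expected-frequency condition failed"
  }
  res <- suppressWarnings(stats::chisq.test(t, correct = yates))
  new_test_result("chi_square", unname(res$statistic), res$p.value, note)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided. Exact null distribution when n1 + n2 <= 20 and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param xs,ys Numeric samples.
#' @return A `dsw_test_result` (statistic is the U of the first sample).
#' @export
mann_whitney <- function(xs, ys) {
  if (length(xs) == 0 || length(ys) == 0) stop("empty sample")
  ties <- anyDuplicated(c(xs, ys)) > 0
  exact <- (length(xs) + length(ys) <= 20) && !ties
  res <- suppressWarnings(stats::wilcox.test(xs, ys, exact = exact,
                                             correct = TRUE))
  new_test_result("mann_whitney", unname(res$statistic), res$p.value,
                  if (exact) "exact" else "normal approximation")
}

#' Normality test (Kolmogorov-Smirnov family)
#'
#' Lilliefors-corrected one-sample KS against a normal with estimated mean
#' and SD (default), or the plain KS test with estimated parameters.
#'
#' @param xs Numeric sample, n >= 4.
#' @param variant `"lilliefors"` (default) or `"ks"`.
#' @return A `dsw_test_result`.
#' @export
ks_normality <- function(xs, variant = c("lilliefors", "ks")) {
  variant <- match.arg(variant)
  if (length(xs) < 4) stop("need n >= 4")
  if (stats::sd(xs) == 0) stop("degenerate sample (zero variance)")
  if (variant == "lilliefors") {
    res <- nortest::lillie.test(xs)
    return(new_test_result("ks_normality", unname(res$statistic), res$p.value,
                           "Lilliefors"))
  }
  res <- suppressWarnings(stats::ks.test(xs, "pnorm", mean(xs), stats::sd(xs)))
  new_test_result("ks_normality", unname(res$statistic), res$p.value,
                  "plain KS, estimated parameters")
}

# Half-up rounding (report-mirroring convention; R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Truncation to 2 decimals: the percentage convention of the summary table
# (28.3/60 -> 47.16).
trunc2 <- function(x) trunc(x * 100) / 100

#' Mean word-error count as a percentage of the 60-word list
#'
#' Truncated (not rounded) to 2 decimals: a mean of 28.3 incorrect words maps
#' to 47.16%.
#' @param mean_incorrect Mean number of incorrect words per student.
#' @param n_words List length (default 60).
#' @return Percentage.
#' @examples
#' pct_of_list(28.3)
#' @export
pct_of_list <- function(mean_incorrect, n_words = 60) {
  trunc2(mean_incorrect / n_words * 100)
}

#' Per-grade error summaries
#'
#' Mean incorrect words per student (1 d.p., half-up) and each group's share
#' of the grade's total misspelled words (2 d.p., half-up).
#'
#' @param totals Data frame like [grade_totals()]: `grade`, `group`,
#'   `n_students`, `total_incorrect`.
#' @return Data frame with `mean_incorrect` and `share_of_grade_errors`
#'   appended.
#' @examples
#' grade_summaries(grade_totals())
#' @export
grade_summaries <- function(totals = grade_totals()) {
  if (any(totals$n_students <= 0)) stop("zero denominators")
  out <- totals
  out$mean_incorrect <- round_half_up(out$total_incorrect / out$n_students, 1)
  out$share_of_grade_errors <- NA_real_
  for (g in unique(out$grade)) {
    sel <- out$grade == g
    tot <- sum(out$total_incorrect[sel])
    if (tot == 0) next   # no misspelled words in this grade: share undefined
    out$share_of_grade_errors[sel] <-
      round_half_up(100 * out$total_incorrect[sel] / tot, 2)
  }
  out
}

#' Distinct error-form counts by category
#'
#' Counts distinct (word, normalized form) pairs per group; every category
#' label carried by a distinct form increments that category once. Totals by
#' spelling class are attached.
#'
#' @param classified Classified response table from [classify_responses()]
#'   (one row per (response, label); summary rows have category `"-"`).
#' @return Data frame group x category with counts, plus attribute
#'   `"class_totals"` (natural/arbitrary/other/total distinct forms per
#'   group).
#' @export
distinct_form_counts <- function(classified) {
  lab <- classified[classified$category != "-" &
                    classified$verdict != "correct", , drop = FALSE]
  grid <- expand.grid(group = c("GD", "GWD"), category = .CATEGORIES,
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  totals <- data.frame(group = c("GD", "GWD"), natural = 0L, arbitrary = 0L,
                       other = 0L, total = 0L, n_distinct_forms = 0L,
                       stringsAsFactors = FALSE)
  if (nrow(lab)) {
    key <- paste(lab$group, lab$word_id, lab$normalized, sep = "\r")
    for (gk in split(lab, key)) {
      g <- gk$group[1]
      cats <- unique(gk$category)
      ti <- totals$group == g
      for (cc in cats) {
        sel <- grid$group == g & grid$category == cc
        grid$n[sel] <- grid$n[sel] + 1L
        cl <- spelling_class(cc)
        totals[[cl]][ti] <- totals[[cl]][ti] + 1L
      }
      totals$n_distinct_forms[ti] <- totals$n_distinct_forms[ti] + 1L
    }
    totals$total <- totals$natural + totals$arbitrary + totals$other
  }
  out <- stats::reshape(grid, idvar = "group", timevar = "category",
                        direction = "wide")
  names(out) <- sub("^n\\.", "", names(out))
  rownames(out) <- NULL
  cat_sums <- rowSums(out[, .CATEGORIES])
  stopifnot(all(cat_sums == totals$total[match(out$group, totals$group)]))
  attr(out, "class_totals") <- totals
  out
}

#' Group summary of incorrect-word counts
#'
#' Per-student incorrect totals by group: mean, SD, median, quartiles, range,
#' and the Mann-Whitney comparison (run after a normality check).
#'
#' @param classified Classified response table from [classify_responses()].
#' @return Data frame, one row per group, with attribute `"mann_whitney"`
#'   (a `dsw_test_result`).
#' @export
group_summary <- function(classified) {
  resp <- unique(classified[, c("student_id", "group", "word_id", "verdict")])
  per_student <- stats::aggregate(verdict != "correct" ~ student_id + group,
                                  data = resp, FUN = sum)
  names(per_student)[3] <- "n_incorrect"
  rows <- lapply(split(per_student, per_student$group), function(d) {
    x <- d$n_incorrect
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 6)
    data.frame(group = d$group[1], n_students = length(x),
               mean = round_half_up(mean(x), 1),
               sd = round_half_up(stats::sd(x), 1),
               median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
               min = min(x), max = max(x),
               pct_of_list = pct_of_list(mean(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mw <- NULL
  if (all(c("GD", "GWD") %in% per_student$group)) {
    mw <- mann_whitney(per_student$n_incorrect[per_student$group == "GD"],
                       per_student$n_incorrect[per_student$group == "GWD"])
  }
  attr(out, "mann_whitney") <- mw
  attr(out, "per_student") <- per_student
  out
}

#' Per-word association tests
#'
#' For each word builds the GD/GWD x correct/incorrect table, applies the
#' selection rule and runs the selected test.
#'
#' @param data Counts table ([table3_counts()] shape) or classified response
#'   table.
#' @return Data frame: `word_id`, `form`, the four cells, `test`, `p_value`
#'   (3 d.p. half-up in `p_round`).
#' @export
word_association_tests <- function(data = table3_counts()) {
  counts_mode <- all(c("gd_correct", "gd_incorrect") %in% names(data))
  ids <- if (counts_mode) data$word_id else sort(unique(data$word_id))
  lex <- dsw_lexicon()
  rows <- lapply(ids, function(id) {
    t <- tryCatch(word_contingency(data, id), error = function(e) NULL)
    if (is.null(t)) {
      return(data.frame(word_id = id, form = lex$form[id],
                        gd_correct = NA_integer_, gd_incorrect = NA_integer_,
                        gwd_correct = NA_integer_, gwd_incorrect = NA_integer_,
                        test = "none", p_value = NA_real_,
                        p_round = NA_real_, stringsAsFactors = FALSE))
    }
    if (all(t[, "incorrect"] == 0L)) {
      return(data.frame(word_id = id, form = lex$form[id],
                        gd_correct = t[1, 1], gd_incorrect = t[1, 2],
                        gwd_correct = t[2, 1], gwd_incorrect = t[2, 2],
                        test = "none", p_value = NA_real_,
                        p_round = NA_real_, stringsAsFactors = FALSE))
    }
    sel <- select_test(t)
    res <- if (sel == "fisher_exact") fisher_exact_2x2(t)
           else chi_square_2x2(t)
    data.frame(word_id = id, form = lex$form[id],
               gd_correct = t[1, 1], gd_incorrect = t[1, 2],
               gwd_correct = t[2, 1], gwd_incorrect = t[2, 2],
               test = sel, p_value = res$p_value,
               p_round = round_half_up(res$p_value, 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
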