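# End-to-end orchestration: classify -> aggregate -> test -> report, in two
# input modes (full response tables, or pre-tabulated per-word counts), plus
# an installed self-test.

#' Classify a response table
#'
#' Runs [classify_spelling()] on every row and returns the long labelled
#' table (one row per (response, label); responses without labels carry a
#' summary row with category `"-"`). Classifications are cached per
#' (word_id, written_form), so repeated forms cost one analysis.
#'
#' @param responses Data frame with `student_id`, `group`, `grade`,
#'   `word_id`, `written_form`.
#' @param config See [classify_config()].
#' @param lexicon Optional preloaded lexicon.
#' @return Long data frame with columns `student_id`, `group`, `grade`,
#'   `word_id`, `written_form`, `normalized`, `verdict`, `category`,
#'   `spelling_class`, `locus`, `rationale`, `notation`.
#' @export
classify_responses <- function(responses, config = classify_config(),
                               lexicon = NULL) {
  lex <- if (is.null(lexicon)) dsw_lexicon() else lexicon
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(responses))
  for (k in seq_len(nrow(responses))) {
    w <- responses$word_id[k]
    form <- responses$written_form[k]
    key <- paste0(w, "\r", form)
    cl <- cache[[key]]
    if (is.null(cl)) {
      cl <- classify_spelling(w, form, config, lex)
      cache[[key]] <- cl
    }
    lab <- cl$labels
    if (nrow(lab) == 0L) {
      lab <- data.frame(category = "-", spelling_class = "-", locus = "",
                        rationale = "", stringsAsFactors = FALSE)
    }
    out[[k]] <- cbind(responses[k, c("student_id", "group", "grade",
                                     "word_id", "written_form")],
                      normalized = if (is.na(cl$normalized)) "" else cl$normalized,
                      verdict = cl$verdict, lab,
                      notation = cl$notation,
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full dictation analysis
#'
#' Orchestrates the pipeline in one of three input modes: a response table
#' (data frame or CSV path), a simulation profile, or a pre-tabulated counts
#' table (counts mode: statistics only, no classification). Produces the
#' classification file, a group summary (mean/SD/median/quartiles/range and
#' Mann-Whitney p), a per-word association table with the selected test and
#' p, a per-grade table, and a per-category distinct-form table.
#'
#' @param responses Response data frame or CSV path (mutually exclusive with
#'   `profile` and `counts`).
#' @param profile A simulation profile; the corpus is generated with it.
#' @param counts A counts table in the [table3_counts()] shape.
#' @param config Classifier configuration.
#' @param output_dir If non-NULL, report tables are written there as CSV.
#' @return List of report tables (class `dsw_report`); in counts mode only
#'   `word_tests` is populated.
#' @examples
#' rep <- run_dictation_analysis(counts = table3_counts())
#' head(rep$word_tests)
#' @export
run_dictation_analysis <- function(responses = NULL, profile = NULL,
                                   counts = NULL,
                                   config = classify_config(),
                                   output_dir = NULL) {
  n_inputs <- sum(!is.null(responses), !is.null(profile), !is.null(counts))
  if (n_inputs != 1L) stop("exactly one of responses/profile/counts required")
  lex <- dsw_lexicon()
  report <- list()
  if (!is.null(counts)) {
    report$word_tests <- word_association_tests(counts)
    report$mode <- "counts"
  } else {
    if (!is.null(profile)) {
      responses <- simulate_dataset(profile, lex)
      report$profile <- profile
    } else if (is.character(responses)) {
      responses <- read_responses(responses)
      report$input_errors <- attr(responses, "errors")
    }
    classified <- classify_responses(responses, config, lex)
    report$classified <- classified
    report$group_summary <- group_summary(classified)
    report$word_tests <- word_association_tests(classified)
    totals <- stats::aggregate(
      verdict ~ grade + group,
      data = unique(classified[, c("student_id", "group", "grade", "word_id",
                                   "verdict")]),
      FUN = function(v) sum(v != "correct"))
    names(totals)[3] <- "total_incorrect"
    nst <- stats::aggregate(student_id ~ grade + group,
                            data = unique(classified[, c("student_id", "group",
                                                         "grade")]),
                            FUN = length)
    names(nst)[3] <- "n_students"
    totals <- merge(nst, totals, by = c("grade", "group"))
    report$grade_summary <- grade_summaries(totals)
    report$category_counts <- distinct_form_counts(classified)
    report$mode <- "responses"
  }
  class(report) <- "dsw_report"
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    for (nm in c("classified", "group_summary", "word_tests", "grade_summary",
                 "category_counts")) {
      if (!is.null(report[[nm]])) {
        utils::write.csv(report[[nm]], file.path(output_dir, paste0(nm, ".csv")),
                         row.names = FALSE, fileEncoding = "UTF-8")
      }
    }
  }
  report
}

#' @export
print.dsw_report <- function(x, ...) {
  cat("<dsw_report> mode:", x$mode, "\n")
  if (!is.null(x$group_summary)) {
    cat("\nGroup summary (incorrect words per student):\n")
    print(x$group_summary)
    mw <- attr(x$group_summary, "mann_whitney")
    if (!is.null(mw)) print(mw)
  }
  if (!is.null(x$grade_summary)) {
    cat("\nPer-grade totals:\n")
    print(x$grade_summary)
  }
  if (!is.null(x$category_counts)) {
    cat("\nDistinct error forms by category:\n")
    print(x$category_counts)
    print(attr(x$category_counts, "class_totals"))
  }
  if (!is.null(x$word_tests)) {
    cat("\nPer-word association tests (first rows):\n")
    print(utils::head(x$word_tests))
  }
  invisible(x)
}

#' Installed self-test
#'
#' Re-runs the embedded benchmarks against the installed package: fixture
#' checksums, taxonomy-table containment, per-word-analysis containment on
#' the unambiguous subset, the five printed Fisher reproductions, and a
#' seeded single-operator corruption round trip.
#'
#' @param n_roundtrip Number of corruption draws (default 200).
#' @param seed RNG seed for the round trip.
#' @return List of counts (printed): each check's pass/total.
#' @export
self_test <- function(n_roundtrip = 200L, seed = 1L) {
  lex <- dsw_lexicon()
  gold <- gold_fixture()
  t3 <- table3_counts()
  res <- list()

  t1 <- gold[gold$source == "tab1", ]
  ok <- 0L
  for (k in seq_len(nrow(t1))) {
    cl <- classify_spelling(t1$word_id[k], t1$form[k], lexicon = lex)
    pred <- if (cl$verdict == "other") "OTHER" else predicted_categories(cl)
    if (all(t1$labels[[k]] %in% pred)) ok <- ok + 1L
  }
  res$table1_containment <- c(pass = ok, total = nrow(t1))

  s41 <- gold[gold$source == "s41" & !gold$ambiguous, ]
  hit <- 0L; tot <- 0L
  for (k in seq_len(nrow(s41))) {
    cl <- classify_spelling(s41$word_id[k], s41$form[k], lexicon = lex)
    pred <- if (cl$verdict == "other") "OTHER" else predicted_categories(cl)
    tot <- tot + length(s41$labels[[k]])
    hit <- hit + sum(s41$labels[[k]] %in% pred)
  }
  res$s41_containment <- c(pass = hit, total = tot)

  fisher_ref <- data.frame(form = c("quando", "ajuda", "feliz", "tenho", "muito"),
                           p = c(0.024, 0.005, 0.002, 0.026, 0.052))
  ok <- 0L
  for (k in seq_len(nrow(fisher_ref))) {
    id <- lex$word_id[lex$form == fisher_ref$form[k]]
    p <- fisher_exact_2x2(word_contingency(t3, id))$p_value
    if (round_half_up(p, 3) == fisher_ref$p[k]) ok <- ok + 1L
  }
  res$fisher_reproduction <- c(pass = ok, total = nrow(fisher_ref))

  set.seed(seed)
  ok <- 0L; n <- 0L
  cats <- c("OIL", "USW", "AAW", "RPG")
  while (n < n_roundtrip) {
    ci <- sample(cats, 1L)
    meta <- dsw_entry(sample.int(60L, 1L), lex)
    form <- tryCatch(corrupt_form(meta, ci, lex), error = function(e) NULL)
    if (is.null(form)) next
    n <- n + 1L
    cl <- classify_spelling(meta, form, lexicon = lex)
    if (ci %in% predicted_categories(cl)) ok <- ok + 1L
  }
  res$corruption_roundtrip <- c(pass = ok, total = n)

  for (nm in names(res)) {
    cat(sprintf("%-22s %d/%d\n", nm, res[[nm]]["pass"], res[[nm]]["total"]))
  }
  invisible(res)
}
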