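# Synthetic dictation corpora with the statistical structure the analysis
# assumes: group-dependent word-error rates and category-specific corruption
# operators. Fully seed-deterministic (base R RNG).

.HOMORGANIC <- list(c("p", "b"), c("t", "d"), c("f", "v"),
                    c("c", "g"), c("s", "z"), c("x", "j"))
.ACCENT_STRIP <- c("á" = "a", "é" = "e", "í" = "i", "ó" = "o",
                   "ú" = "u", "â" = "a", "ê" = "e", "ô" = "o")

#' Default simulation profile
#'
#' Study-design defaults: per-group word-error rates 0.4716 (GD) and 0.0716
#' (GWD); grades 3-6 with 10, 8, 4 and 8 students per group; category mix
#' proportional to the distinct-error-form counts per group (GD: IPG_1 124,
#' IPG_2 91, OIL 80, RPG 60, USW 24, AAW 13, ASS 7; GWD: IPG_1 17, IPG_2 12,
#' OIL 7, USW 7, RPG 4, AAW 4, ASS 0, OTHER 1).
#'
#' @param seed Integer seed stored in the profile.
#' @param multi_error_rate Probability of a second corruption operator on an
#'   already-misspelled word (default 0.1).
#' @return A `sim_profile` list: `groups` (per-group `word_error_rate` and
#'   `category_mix`), `grades` (grade, group, n_students), `multi_error_rate`,
#'   `seed`.
#' @export
default_profile <- function(seed = 1L, multi_error_rate = 0.1) {
  gd_mix <- c(RPG = 60, OIL = 80, ASS = 7, USW = 24,
              IPG_1 = 124, IPG_2 = 91, AAW = 13, OTHER = 0)
  gwd_mix <- c(RPG = 4, OIL = 7, ASS = 0, USW = 7,
               IPG_1 = 17, IPG_2 = 12, AAW = 4, OTHER = 1)
  grades <- expand.grid(grade = 3:6, group = c("GD", "GWD"),
                        stringsAsFactors = FALSE)
  grades$n_students <- c(10L, 8L, 4L, 8L, 10L, 8L, 4L, 8L)
  structure(list(
    groups = list(
      GD = list(word_error_rate = 0.4716, category_mix = gd_mix / sum(gd_mix)),
      GWD = list(word_error_rate = 0.0716, category_mix = gwd_mix / sum(gwd_mix))
    ),
    grades = grades,
    multi_error_rate = multi_error_rate,
    seed = as.integer(seed)
  ), class = "sim_profile")
}

#' @export
print.sim_profile <- function(x, ...) {
  cat("<sim_profile> seed", x$seed, "\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %s: rate %.4f, mix %s\n", g, x$groups[[g]]$word_error_rate,
                paste(sprintf("%s=%.2f", names(x$groups[[g]]$category_mix),
                              x$groups[[g]]$category_mix), collapse = " ")))
  }
  invisible(x)
}

# candidate sets per (form, category), memoised for the session
.cand_cache <- new.env(parent = emptyenv())

applicability_error <- function(msg) {
  stop(structure(class = c("applicability_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# structural well-formedness: `cand` must re-segment exactly to `units`
segments_to <- function(cand, units) {
  got <- tryCatch(segment_graphemes(cand)$units, error = function(e) NULL)
  !is.null(got) && length(got) == length(units) && all(got == units)
}

join_units <- function(units) paste(units, collapse = "")

#' Apply one category-consistent corruption operator
#'
#' RPG swaps a grapheme for a homorganic partner (p/b, t/d, f/v, c/g, s/z,
#' x/j) where the swap changes the reading; OIL deletes or inserts one
#' grapheme; ASS transposes two adjacent units or migrates a semivowel; USW
#' removes a token boundary (multiword targets) or splits at a syllable
#' boundary; IPG_1/IPG_2 substitute within the rule table's licensed
#' alternatives (digraph simplification, tilde stripping, posttonic/pretonic
#' vowel swaps, coda-nasal letters, sibilant family, ...); AAW strips the
#' acute/circumflex; OTHER emits the listed lexical form. Uses the R RNG
#' stream; the result never equals the target.
#'
#' @param target Word id, form, or lexicon entry.
#' @param category Category code.
#' @param lexicon Optional preloaded lexicon.
#' @return Corrupted written form (character scalar).
#' @examples
#' set.seed(1)
#' corrupt_form("embaixo", "USW")
#' corrupt_form("árvore", "AAW")
#' @export
corrupt_form <- function(target, category, lexicon = NULL) {
  meta <- resolve_target(target, lexicon)
  key <- paste0(meta$form, "\r", category)
  cached <- .cand_cache[[key]]
  if (!is.null(cached)) {
    if (length(cached) == 0) {
      applicability_error(sprintf("category %s not applicable to '%s'",
                                  category, meta$form))
    }
    return(cached[sample.int(length(cached), 1L)])
  }
  gs <- segment_graphemes(meta$form)
  cands <- switch(category,
    RPG = rpg_candidates(meta, gs),
    OIL = oil_candidates(meta, gs),
    ASS = ass_candidates(meta, gs),
    USW = usw_candidates(meta, gs),
    IPG_1 = ipg1_candidates(meta, gs),
    IPG_2 = ipg2_candidates(meta, gs),
    AAW = aaw_candidates(meta, gs),
    OTHER = other_candidates(meta),
    stop("unknown category: ", category))
  cands <- setdiff(unique(cands), meta$form)
  .cand_cache[[key]] <- cands
  if (length(cands) == 0) {
    applicability_error(sprintf("category %s not applicable to '%s'",
                                category, meta$form))
  }
  cands[sample.int(length(cands), 1L)]
}

with_unit <- function(gs, i, repl) {
  u <- gs$units
  u[i] <- repl
  out <- u
  for (b in rev(gs$boundaries)) out <- append(out, " ", after = b)
  paste(out, collapse = "")
}

without_unit <- function(gs, i) {
  u <- gs$units
  keep <- setdiff(seq_along(u), i)
  bnd <- vapply(gs$boundaries, function(b) b - sum(i <= b), numeric(1))
  out <- u[keep]
  for (b in rev(bnd)) if (b > 0 && b < length(out)) out <- append(out, " ", after = b)
  paste(out, collapse = "")
}

sub_category_of <- function(meta, gs, i, repl) {
  cand <- with_unit(gs, i, repl)
  cl <- tryCatch(classify_spelling(meta, cand),
                 error = function(e) NULL)
  if (is.null(cl) || cl$verdict != "misspelled") return(NULL)
  labs <- predicted_categories(cl)
  if (length(labs) == 1L) list(form = cand, category = labs) else NULL
}

# single-substitution candidates whose lone predicted label equals `want`
single_sub_candidates <- function(meta, gs, pairs, want) {
  out <- character(0)
  for (i in seq_along(gs$units)) {
    g <- gs$units[i]
    for (p in pairs) {
      if (g %in% p) {
        for (repl in setdiff(p, g)) {
          if (repl %in% .TILDE_VOWELS) next  # tilde is stripped, never added
          expected <- gs$units
          expected[i] <- repl
          cand <- with_unit(gs, i, repl)
          if (!segments_to(cand, expected)) next
          hit <- sub_category_of(meta, gs, i, repl)
          if (!is.null(hit) && hit$category == want) out <- c(out, hit$form)
        }
      }
    }
  }
  out
}

rpg_candidates <- function(meta, gs) {
  single_sub_candidates(meta, gs, .HOMORGANIC, "RPG")
}

oil_candidates <- function(meta, gs) {
  out <- character(0)
  n <- length(gs$units)
  # deletions: any unit except word-initial silent h; result must re-segment
  # to exactly the remaining units (no digraph fusion)
  for (i in seq_len(n)) {
    if (gs$units[i] == "h") next
    cand <- without_unit(gs, i)
    if (!nzchar(gsub(" ", "", cand))) next
    if (segments_to(gsub("^ | $", "", cand), gs$units[-i])) out <- c(out, cand)
  }
  # insertions of one plain letter that stays a unit of its own
  for (i in 0:n) {
    for (ch in c("a", "e", "i", "o", "u", "r", "l", "n", "m", "t", "s", "p")) {
      expected <- append(gs$units, ch, after = i)
      cand <- join_units(expected)
      if (!segments_to(cand, expected)) next
      # keep it a pure indel under the classifier (no doubled-letter or
      # accent-rule reinterpretation)
      cl <- tryCatch(classify_spelling(meta, cand), error = function(e) NULL)
      if (!is.null(cl) && cl$verdict == "misspelled" &&
          identical(predicted_categories(cl), "OIL")) {
        out <- c(out, cand)
      }
    }
  }
  out
}

ass_candidates <- function(meta, gs) {
  out <- character(0)
  n <- length(gs$units)
  for (i in seq_len(n - 1L)) {
    if (gs$units[i] == gs$units[i + 1L]) next
    if (i %in% gs$boundaries) next   # do not transpose across a space
    expected <- gs$units
    expected[c(i, i + 1L)] <- expected[c(i + 1L, i)]
    cand <- join_units(expected)
    if (length(gs$boundaries)) {
      u <- expected
      for (b in rev(gs$boundaries)) u <- append(u, " ", after = b)
      cand <- paste(u, collapse = "")
    }
    if (!segments_to(gsub(" ", "", cand), expected)) next
    cl <- tryCatch(classify_spelling(meta, cand), error = function(e) NULL)
    if (!is.null(cl) && "ASS" %in% predicted_categories(cl)) out <- c(out, cand)
  }
  out
}

usw_candidates <- function(meta, gs) {
  out <- character(0)
  if (isTRUE(meta$multiword)) {
    out <- c(out, gsub(" ", "", meta$form, fixed = TRUE))
  } else if (meta$n_syllables >= 2L) {
    sylls <- strsplit(meta$syllab, ".", fixed = TRUE)[[1]]
    for (k in seq_len(length(sylls) - 1L)) {
      out <- c(out, paste(paste(sylls[seq_len(k)], collapse = ""),
                          paste(sylls[-seq_len(k)], collapse = "")))
    }
  }
  out
}

ipg1_candidates <- function(meta, gs) {
  pairs <- list(c("rr", "r"), c("gu", "g"), c("qu", "q"),
                c("ã", "a"), c("õ", "o"),
                c("e", "i"), c("o", "u"), c("u", "l"), c("u", "o"),
                c("m", "n"), c("j", "g"))
  single_sub_candidates(meta, gs, pairs, "IPG_1")
}

ipg2_candidates <- function(meta, gs) {
  pairs <- list(c("s", "z"), c("s", "ss"), c("s", "ç"), c("ss", "ç"),
                c("ss", "c"), c("s", "c"), c("ç", "c"), c("z", "ss"),
                c("x", "ch"), c("g", "j"), c("e", "i"), c("o", "u"),
                c("l", "u"), c("l", "o"), c("m", "n"))
  out <- single_sub_candidates(meta, gs, pairs, "IPG_2")
  # word-initial silent-h omission is also lexically arbitrary
  if (gs$units[1] == "h") {
    out <- c(out, without_unit(gs, 1L))
  }
  out
}

aaw_candidates <- function(meta, gs) {
  out <- character(0)
  for (i in seq_along(gs$units)) {
    g <- gs$units[i]
    if (g %in% names(.ACCENT_STRIP)) {
      out <- c(out, with_unit(gs, i, .ACCENT_STRIP[[g]]))
    }
  }
  out
}

other_candidates <- function(meta) {
  map <- c("tenho" = "temum", "almoço" = "almoção", "futebol" = "futball")
  if (meta$form %in% names(map)) unname(map[meta$form]) else character(0)
}

# Second-operator corruption of an already-misspelled string: a
# category-directed structural edit. When the target metadata is supplied the
# candidates are filtered so the added edit actually carries the requested
# category label; otherwise the edit is structural only. Returns the input
# unchanged when the category has no admissible edit on the string (the
# caller keeps the single-error form).
corrupt_further <- function(form, category = "OIL", meta = NULL) {
  gs <- tryCatch(segment_graphemes(normalize_form(form)),
                 error = function(e) NULL)
  if (is.null(gs) || length(gs$units) < 2L) return(form)
  n <- length(gs$units)
  u <- gs$units
  swap_pairs <- function(pairs) {
    hits <- list()
    for (i in seq_len(n)) {
      for (p in pairs) {
        if (u[i] %in% p) {
          for (repl in setdiff(p, u[i])) {
            cand <- with_unit(gs, i, repl)
            if (segments_to(gsub(" ", "", cand), replace(u, i, repl))) {
              hits[[length(hits) + 1L]] <- cand
            }
          }
        }
      }
    }
    unlist(hits)
  }
  cands <- switch(category,
    OIL = {
      dels <- vapply(seq_len(n), function(i) without_unit(gs, i), character(1))
      keep <- vapply(seq_len(n), function(i) {
        segments_to(gsub("^ | $|  ", "", dels[i]), u[-i])
      }, logical(1))
      dels[keep]
    },
    ASS = {
      hits <- character(0)
      for (i in seq_len(n - 1L)) {
        if (u[i] == u[i + 1L] || i %in% gs$boundaries) next
        sw <- replace(u, c(i, i + 1L), u[c(i + 1L, i)])
        cand <- join_units(sw)
        if (segments_to(cand, sw)) hits <- c(hits, cand)
      }
      hits
    },
    RPG = swap_pairs(.HOMORGANIC),
    IPG_1 = swap_pairs(list(c("rr", "r"), c("gu", "g"), c("m", "n"))),
    IPG_2 = swap_pairs(list(c("s", "z"), c("ss", "s"), c("ç", "s"),
                            c("e", "i"), c("o", "u"))),
    AAW = {
      hits <- character(0)
      for (i in seq_len(n)) {
        if (u[i] %in% names(.ACCENT_STRIP)) {
          hits <- c(hits, with_unit(gs, i, .ACCENT_STRIP[[u[i]]]))
        }
      }
      hits
    },
    character(0))
  cands <- setdiff(unique(stats::na.omit(cands)), form)
  cands <- cands[nzchar(gsub(" ", "", cands))]
  if (!is.null(meta) && length(cands)) {
    keep <- vapply(cands, function(cand) {
      cl <- tryCatch(classify_spelling(meta, cand), error = function(e) NULL)
      !is.null(cl) && cl$verdict == "misspelled" &&
        category %in% predicted_categories(cl)
    }, logical(1))
    cands <- cands[keep]
  }
  if (length(cands) == 0) return(form)
  cands[sample.int(length(cands), 1L)]
}

# Applicability-aware per-word category weights. Rejection against a fixed
# word list would shift mass toward the always-applicable operators (OIL is
# applicable to every word, AAW only to the accented ones). Per-category
# weights are calibrated by iterative proportional fitting so that the
# corpus-level expected category distribution equals the profile's mix (up
# to categories whose coverage makes the target unreachable).
word_category_weights <- function(mix, applicable, iters = 200L) {
  mix <- mix / sum(mix)
  reachable <- colSums(applicable) > 0 & mix > 0
  v <- ifelse(reachable, mix, 0)
  A <- applicable * 1
  for (it in seq_len(iters)) {
    W <- sweep(A, 2, v, "*")
    Z <- rowSums(W)
    W <- W[Z > 0, , drop = FALSE] / Z[Z > 0]
    realized <- colMeans(W)
    adj <- ifelse(reachable & realized > 0, mix / realized, 1)
    v <- v * adj
    v <- v / sum(v)
    if (max(abs(adj[reachable] - 1)) < 1e-10) break
  }
  W <- sweep(A, 2, v, "*")
  sweep(W, 1, rowSums(W), "/")
}

#' Simulate a dictation corpus
#'
#' For each student and each of the 60 target words, with the group's
#' word-error rate a corruption category is drawn from the category mix and
#' applied ([corrupt_form()]); with `multi_error_rate` a second structural
#' edit is added. Otherwise the correct form is emitted. Deterministic given
#' the profile seed.
#'
#' @param profile A [default_profile()]-shaped profile.
#' @param lexicon Optional preloaded lexicon.
#' @return Response data frame: `student_id`, `group`, `grade`, `word_id`,
#'   `written_form`, plus `injected` (the drawn category, `""` when correct).
#' @export
simulate_dataset <- function(profile = default_profile(), lexicon = NULL) {
  lex <- if (is.null(lexicon)) dsw_lexicon() else lexicon
  entries <- lapply(1:60, dsw_entry, lexicon = lex)
  cats <- names(profile$groups[[1]]$category_mix)
  # candidate applicability per word x category (deterministic; warms the
  # candidate cache before any random draw)
  applicable <- matrix(FALSE, 60L, length(cats), dimnames = list(NULL, cats))
  for (w in 1:60) {
    for (ci in cats) {
      key <- paste0(entries[[w]]$form, "\r", ci)
      if (is.null(.cand_cache[[key]])) {
        try(corrupt_form(entries[[w]], ci, lex), silent = TRUE)
      }
      applicable[w, ci] <- length(.cand_cache[[key]]) > 0
    }
  }
  set.seed(profile$seed)
  rows <- vector("list", 0)
  for (k in seq_len(nrow(profile$grades))) {
    grade <- profile$grades$grade[k]
    group <- profile$grades$group[k]
    gp <- profile$groups[[group]]
    wmix <- word_category_weights(gp$category_mix, applicable)
    for (s in seq_len(profile$grades$n_students[k])) {
      sid <- sprintf("%s%d_%02d", group, grade, s)
      for (w in 1:60) {
        meta <- entries[[w]]
        if (stats::runif(1) < gp$word_error_rate) {
          cat_drawn <- sample(cats, 1L, prob = wmix[w, ])
          form <- tryCatch(corrupt_form(meta, cat_drawn, lex),
                           error = function(e) NULL)
          if (is.null(form)) { form <- meta$form; cat_drawn <- "" }
          if (nzchar(cat_drawn) && cat_drawn != "OTHER" &&
              stats::runif(1) < profile$multi_error_rate) {
            cat2 <- sample(cats, 1L, prob = gp$category_mix)
            form2 <- corrupt_further(form, cat2, meta)
            if (normalize_form(form2) != meta$form) form <- form2
          }
          rows[[length(rows) + 1L]] <- data.frame(
            student_id = sid, group = group, grade = grade, word_id = w,
            written_form = form, injected = cat_drawn,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            student_id = sid, group = group, grade = grade, word_id = w,
            written_form = meta$form, injected = "",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
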