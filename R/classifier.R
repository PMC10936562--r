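# Semiological classification of a (target, written form) pair.
#
# Categories: natural spelling -- RPG (regular phoneme/grapheme correspondence
# errors: sound-changing substitutions), OIL (omission or insertion of
# letters), ASS (alteration in the syllabic structure), USW (unconventional
# segmentation of words); arbitrary spelling -- IPG_1 (sound-preserving
# violation of a context/morphology-dependent rule), IPG_2 (sound-preserving
# lexically arbitrary choice), AAW (alteration in accentuation); plus OTHER.
#
# The mapping from aligned edits to categories is a precedent rule cascade
# (see the methods vignette for each precedent's justification).

.CATEGORIES <- c("RPG", "OIL", "ASS", "USW", "IPG_1", "IPG_2", "AAW", "OTHER")
.NATURAL <- c("RPG", "OIL", "ASS", "USW")
.ARBITRARY <- c("IPG_1", "IPG_2", "AAW")
.SIBILANT_PHONES <- c("s", "z", "S")

#' Spelling class of a category
#'
#' @param category Character vector of category codes.
#' @return `"natural"`, `"arbitrary"` or `"other"`.
#' @export
spelling_class <- function(category) {
  ifelse(category %in% .NATURAL, "natural",
         ifelse(category %in% .ARBITRARY, "arbitrary", "other"))
}

#' Classifier configuration
#'
#' @param similarity_threshold Responses with grapheme similarity below this
#'   are OTHER (default 0.5).
#' @param other_forms Lexical OTHER list (exact-match forms).
#' @return A list used by [classify_spelling()].
#' @export
classify_config <- function(similarity_threshold = 0.5,
                            other_forms = other_form_list()) {
  list(similarity_threshold = similarity_threshold,
       other_forms = other_forms)
}

resolve_target <- function(target, lexicon = NULL) {
  if (is.list(target) && !is.null(target$form)) return(target)
  dsw_entry(target, lexicon)
}

new_label <- function(category, locus = "", rationale = "") {
  data.frame(category = category, spelling_class = spelling_class(category),
             locus = locus, rationale = rationale, stringsAsFactors = FALSE)
}

empty_labels <- function() {
  data.frame(category = character(0), spelling_class = character(0),
             locus = character(0), rationale = character(0),
             stringsAsFactors = FALSE)
}

new_classification <- function(meta, written_form, normalized, verdict,
                               labels, notation = "") {
  structure(list(word_id = meta$word_id %||% NA_integer_,
                 target = meta$form,
                 written_form = written_form,
                 normalized = normalized,
                 verdict = verdict,
                 labels = labels,
                 notation = notation),
            class = "spelling_classification")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spelling_classification <- function(x, ...) {
  cat(sprintf("<classification> '%s' -> '%s': %s\n",
              x$target, x$written_form, x$verdict))
  if (nrow(x$labels)) {
    for (k in seq_len(nrow(x$labels))) {
      cat(sprintf("  %-5s (%s) %s %s\n", x$labels$category[k],
                  x$labels$spelling_class[k], x$labels$locus[k],
                  x$labels$rationale[k]))
    }
  }
  if (nzchar(x$notation)) cat(" ", x$notation, "\n")
  invisible(x)
}

# token-final / token-initial tests for a target grapheme index
tok_final <- function(gs, i) i == length(gs$units) || i %in% gs$boundaries
tok_initial <- function(gs, i) i == 1L || (i - 1L) %in% gs$boundaries

unit_is_w <- function(units, i) {
  p <- unit_phones(units, i)
  length(p) == 1L && p == "w"
}

#' Classify one written dictation response
#'
#' Decision cascade: (1) normalize; equality with the target is `correct`.
#' (2) OTHER gate: blank/non-letter input, lexical OTHER forms, or grapheme
#' similarity below threshold. (3) boundary layer: every hypo/hypersegmentation
#' gives a USW label. (4) accent layer: acute/circumflex-only differences on
#' aligned vowels give AAW. (5) per-edit layer: substitutions and indels are
#' labeled by the precedent rule cascade; adjacent transpositions, migrated
#' graphemes (deleted in one syllable, inserted in another) and
#' syllable-restructured anagrams give ASS. Multi-label: one response can
#' carry several categories.
#'
#' @param target A word_id (1-60), a target form, or a lexicon entry list.
#' @param written_form Raw written response.
#' @param config See [classify_config()].
#' @param lexicon Optional preloaded [dsw_lexicon()].
#' @return A `spelling_classification`: verdict (`correct` / `misspelled` /
#'   `other`) plus a label data frame (category, spelling_class, locus,
#'   rationale).
#' @examples
#' classify_spelling("de repente", "derepente")
#' classify_spelling("exame", "isami")
#' classify_spelling("árvore", "arvore")
#' @export
classify_spelling <- function(target, written_form,
                              config = classify_config(), lexicon = NULL) {
  meta <- resolve_target(target, lexicon)
  norm <- tryCatch(normalize_form(written_form), error = function(e) NA_character_)
  if (is.na(norm)) {
    return(new_classification(meta, written_form, NA_character_, "other",
                              new_label("OTHER", rationale = "blank")))
  }
  if (norm == meta$form) {
    return(new_classification(meta, written_form, norm, "correct",
                              empty_labels()))
  }
  rgs <- tryCatch(segment_graphemes(norm), error = function(e) NULL)
  if (is.null(rgs)) {
    return(new_classification(meta, written_form, norm, "other",
                              new_label("OTHER", rationale = "non-letter")))
  }
  if (norm %in% config$other_forms) {
    return(new_classification(meta, written_form, norm, "other",
                              new_label("OTHER", rationale = "lexical-other-list")))
  }
  tgs <- segment_graphemes(meta$form)
  script <- align_graphemes(tgs, rgs, meta)
  mx <- max(length(tgs$units), length(rgs$units))
  sim <- max(0, min(1, 1 - attr(script, "cost") / mx))
  if (sim < config$similarity_threshold) {
    return(new_classification(meta, written_form, norm, "other",
                              new_label("OTHER",
                                        rationale = sprintf("similarity=%.2f", sim))))
  }

  labels <- list()
  add <- function(category, locus = "", rationale = "") {
    labels[[length(labels) + 1L]] <<- new_label(category, locus, rationale)
  }

  # (3) boundary layer
  bops <- boundary_diff(tgs, rgs, meta, script)
  for (k in seq_len(nrow(bops))) {
    add("USW", locus = sprintf("boundary@%s", bops$r_from[k]),
        rationale = if (bops$kind[k] == "join") "hyposegmentation"
                    else "hypersegmentation")
  }

  tu <- attr(script, "target")
  ru <- attr(script, "response")
  consumed <- rep(FALSE, nrow(script))
  kinds <- script$kind
  locus_of <- function(k) sprintf("%d:%s", script$t_from[k],
                                  if (nzchar(script$t_sur[k])) script$t_sur[k]
                                  else script$r_sur[k])

  # tilde omission possibly compensated by an adjacent nasal letter
  for (k in which(kinds == "substitution")) {
    if (script$t_sur[k] %in% .TILDE_VOWELS &&
        base_vowel(script$r_sur[k]) == base_vowel(script$t_sur[k])) {
      nx <- which(kinds == "insertion" & script$r_from == script$r_to[k] + 1L &
                  script$r_sur %in% c("m", "n") & !consumed)
      if (length(nx)) consumed[nx[1]] <- TRUE
      consumed[k] <- TRUE
      add("IPG_1", locus_of(k), "tilde-nasalization")
    }
  }
  # qu -> c + inserted u (irregular QU/CU syllables)
  for (k in which(kinds == "substitution")) {
    if (consumed[k]) next
    if (script$t_sur[k] == "qu" && script$r_sur[k] == "c") {
      nx <- which(kinds == "insertion" & script$r_from == script$r_to[k] + 1L &
                  script$r_sur == "u" & !consumed)
      if (length(nx)) {
        consumed[c(k, nx[1])] <- TRUE
        add("IPG_2", locus_of(k), "qu/cu-irregular")
      }
    }
  }
  # ASS: adjacent transpositions
  for (k in which(kinds == "transposition")) {
    consumed[k] <- TRUE
    add("ASS", locus_of(k), "adjacent-transposition")
  }
  # ASS: grapheme migration (same grapheme, or two /w/ spellings, deleted in
  # one syllable and inserted in another)
  syll_of_t <- function(i) {
    i <- max(1L, min(i, length(meta$syllable_of)))
    meta$syllable_of[i]
  }
  dels <- which(kinds == "deletion" & !consumed)
  inss <- which(kinds == "insertion" & !consumed)
  for (d in dels) {
    if (consumed[d]) next
    for (j in inss) {
      if (consumed[j]) next
      same <- script$t_sur[d] == script$r_sur[j]
      wpair <- script$t_sur[d] %in% c("l", "u", "o") &&
               script$r_sur[j] %in% c("l", "u", "o")
      spair <- script$t_sur[d] %in% c("s", "ss", "ç", "c", "sc", "sç") &&
               script$r_sur[j] %in% c("s", "ss", "ç", "c", "sc", "sç")
      if (!(same || wpair || spair)) next
      if (syll_of_t(script$t_from[d]) != syll_of_t(script$t_to[j])) {
        consumed[c(d, j)] <- TRUE
        add("ASS", locus_of(d), "grapheme-migration")
        break
      }
    }
  }
  # ASS: syllable restructuring (same letters, different order)
  if (!any(vapply(labels, function(l) l$category == "ASS", logical(1)))) {
    strip_all <- function(units) paste(base_vowel(units), collapse = "")
    ta <- strip_all(tu); ra <- strip_all(ru)
    if (ta != ra &&
        paste(sort(strsplit(ta, "")[[1]]), collapse = "") ==
        paste(sort(strsplit(ra, "")[[1]]), collapse = "")) {
      add("ASS", "", "syllable-restructuring")
    }
  }
  # remaining per-edit labels
  for (k in seq_len(nrow(script))) {
    if (consumed[k] || kinds[k] == "match") next
    if (kinds[k] == "substitution") {
      a <- script$t_sur[k]; b <- script$r_sur[k]
      if (accent_only_pair(a, b)) {
        add("AAW", locus_of(k), "accent-alteration")
      } else {
        lab <- substitution_category(script, k, tgs, meta, rgs)
        add(lab$category, locus_of(k), lab$rationale)
      }
    } else {
      lab <- indel_category(script, k, tgs, meta)
      add(lab$category, locus_of(k), lab$rationale)
    }
  }
  labels <- if (length(labels)) do.call(rbind, labels) else empty_labels()
  new_classification(meta, written_form, norm, "misspelled", labels,
                     edit_notation(script))
}

# Precedent cascade for one substitution edit. Returns list(category, rationale).
# "final" requires token-finality on BOTH sides: in a hyposegmented response
# the formerly word-final nasal of the first token is internal (ensima-type
# IPG_1), while homem -> homen stays a final-nasal IPG_2.
substitution_category <- function(script, k, tgs, meta, rgs = NULL) {
  tu <- attr(script, "target"); ru <- attr(script, "response")
  ti <- script$t_from[k]; rj <- script$r_from[k]
  gt <- tu[ti]; gr <- ru[rj]
  x_sound <- if (isTRUE(meta$x_reads_z)) "z" else NULL
  pt <- unit_phones(tu, ti, x_sound)
  pr <- unit_phones(ru, rj, NULL)
  final <- tok_final(tgs, ti) &&
    (is.null(rgs) || tok_final(rgs, rj))
  nxt <- if (ti < length(tu)) tu[ti + 1L] else ""
  res <- function(category, rationale) list(category = category,
                                            rationale = rationale)

  # tilde involved but not resolved above (e.g. final -ão morpheme)
  if (gt %in% .TILDE_VOWELS || gr %in% .TILDE_VOWELS) {
    return(res("IPG_1", "tilde-nasalization"))
  }
  # per-word morphological slot rule (e.g. the <ss> of 'disse')
  if (nzchar(meta$slot_rules) &&
      grepl(paste0("(^|;)", gt, "=morph"), meta$slot_rules) &&
      all(pr %in% .SIBILANT_PHONES)) {
    return(res("IPG_1", paste0("morph-", gt)))
  }
  # lexical x -> /z/ words: replacing <x> by another /z//s/ spelling violates
  # the (quasi-regular) ex+vowel reading rule
  if (isTRUE(meta$x_reads_z) && gt == "x" && all(pr %in% .SIBILANT_PHONES)) {
    return(res("IPG_1", "x-for-/z/"))
  }
  # x <-> ch for the /S/ fricative: contextual after initial <en> or after a
  # diphthong, lexical elsewhere
  if ((gt == "x" && gr == "ch") || (gt == "ch" && gr == "x")) {
    en_initial <- grepl("^en", meta$form)
    diphthong <- ti > 2L && is_vowel_unit(tu[ti - 1L]) && is_vowel_unit(tu[ti - 2L])
    return(res(if (en_initial || diphthong) "IPG_1" else "IPG_2",
               "x/ch-fricative"))
  }
  # digraph qu/gu simplification (and c -> qu inflation)
  if ((gt == "gu" && gr == "g") || (gt == "qu" && gr == "q")) {
    return(res("IPG_1", "digraph-simplification"))
  }
  if (gt == "c" && gr == "qu") return(res("IPG_1", "c/qu-for-/k/"))
  # rr digraph
  if ((gt == "rr" && gr == "r") || (gt == "r" && gr == "rr")) {
    return(res("IPG_1", "rr-digraph"))
  }
  # sibilant family: both spellings read /s/, /z/ or coda /S/ in context
  if (all(pt %in% .SIBILANT_PHONES) && all(pr %in% .SIBILANT_PHONES)) {
    return(res("IPG_2", "sibilant-choice"))
  }
  # g/j before e,i: arbitrary; j -> g elsewhere follows the contextual reading
  if (gt %in% c("g", "j") && gr %in% c("g", "j") &&
      base_vowel(nxt) %in% c("e", "i")) {
    return(res("IPG_2", "g/j-choice"))
  }
  if (gt == "j" && gr == "g") return(res("IPG_1", "j/g-contextual"))
  # nasal coda letter
  if (gt %in% c("m", "n") && gr %in% c("m", "n")) {
    if (final) return(res("IPG_2", "final-nasal-m/n"))
    if (!is_vowel_unit(nxt)) return(res("IPG_1", "nasal-coda-letter"))
    return(res("RPG", "phoneme-change"))
  }
  # final nasal written as an oral glide/vowel (-em -> -ei)
  if (gt %in% c("m", "n") && final && is_vowel_unit(gr)) {
    return(res("IPG_2", "final-nasal-diphthong"))
  }
  # semivowel /w/ spellings l/u/o
  if (unit_is_w(tu, ti) && unit_is_w(ru, rj)) {
    if (final && isTRUE(meta$verb_past)) {
      return(res("IPG_1", "past-tense-semivowel"))
    }
    return(res("IPG_2", "semivowel-l/u/o"))
  }
  if (final && isTRUE(meta$verb_past) && gt == "u" && gr %in% c("o", "l", "ó")) {
    return(res("IPG_1", "past-tense-semivowel"))
  }
  # unstressed vowel pairs e/i and o/u
  vpair <- (base_vowel(gt) %in% c("e", "i") && base_vowel(gr) %in% c("e", "i")) ||
           (base_vowel(gt) %in% c("o", "u") && base_vowel(gr) %in% c("o", "u"))
  if (vpair && is_vowel_unit(gt) && is_vowel_unit(gr)) {
    if (final) {
      paroxytone <- (meta$n_syllables - meta$stress) == 1L
      return(res(if (paroxytone) "IPG_1" else "IPG_2",
                 "final-posttonic-vowel"))
    }
    if (meta$syllable_of[ti] < meta$stress) {
      return(res("IPG_2", "pretonic-vowel"))
    }
  }
  # fallback: sound-preserving -> rule lookup; sound-changing -> RPG
  equiv <- length(pt) == length(pr) && all(pt == pr) &&
    !(is_vowel_unit(gt) && is_vowel_unit(gr) &&
      coda_nasal_after(tu, ti) != coda_nasal_after(ru, rj))
  if (equiv) {
    rules <- lookup_rules(tgs, ti, meta)
    if (nrow(rules) && rules$rule_class[1] %in% c("contextual", "morphological")) {
      return(res("IPG_1", rules$rule_id[1]))
    }
    return(res("IPG_2", "lexical-equivalent"))
  }
  res("RPG", "phoneme-change")
}

# Category for one insertion/deletion edit.
indel_category <- function(script, k, tgs, meta) {
  if (script$kind[k] == "deletion" && script$t_sur[k] == "h" &&
      tok_initial(tgs, script$t_from[k])) {
    return(list(category = "IPG_2", rationale = "h-omission"))
  }
  list(category = "OIL",
       rationale = if (script$kind[k] == "deletion") "omission" else "insertion")
}

#' Label one substitution edit
#'
#' Exposes the precedent cascade for a single substitution op of an edit
#' script (see [align_graphemes()]).
#'
#' @param script An `edit_script`.
#' @param k Row index of a substitution op.
#' @param target A target identifier accepted by [classify_spelling()].
#' @return One-row label data frame.
#' @export
label_substitution <- function(script, k, target) {
  stopifnot(script$kind[k] == "substitution")
  meta <- resolve_target(target)
  tgs <- segment_graphemes(meta$form)
  lab <- substitution_category(script, k, tgs, meta)
  new_label(lab$category, sprintf("%d:%s", script$t_from[k], script$t_sur[k]),
            lab$rationale)
}

#' Label one insertion/deletion edit
#'
#' @inheritParams label_substitution
#' @export
label_indel <- function(script, k, target) {
  stopifnot(script$kind[k] %in% c("insertion", "deletion"))
  meta <- resolve_target(target)
  tgs <- segment_graphemes(meta$form)
  lab <- indel_category(script, k, tgs, meta)
  new_label(lab$category,
            sprintf("%d:%s", script$t_from[k],
                    if (nzchar(script$t_sur[k])) script$t_sur[k] else script$r_sur[k]),
            lab$rationale)
}

#' OTHER-category gate
#'
#' TRUE when a written form is routed to OTHER: blank or non-letter input,
#' grapheme similarity below the threshold, or membership in the lexical
#' OTHER list.
#'
#' @inheritParams classify_spelling
#' @return Logical flag.
#' @examples
#' is_other_form("tenho", "temum")
#' is_other_form("casa", "casa")
#' @export
is_other_form <- function(target, written_form, config = classify_config(),
                          lexicon = NULL) {
  cl <- classify_spelling(target, written_form, config, lexicon)
  cl$verdict == "other"
}

#' Categories predicted for a response
#'
#' Convenience accessor: unique category codes of a classification.
#' @param x A `spelling_classification`.
#' @return Character vector.
#' @export
predicted_categories <- function(x) unique(x$labels$category)
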