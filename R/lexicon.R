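# The 60-entry 'Dyslexic Sight Words' (DSW) dictation lexicon, embedded as a
# constant and exported as a delimited resource (inst/extdata/dsw_lexicon.csv,
# identical content). Syllabification and stress are hand-encoded per entry;
# responses inherit the target's metadata through alignment. slot_rules carry
# per-word orthographic-rule overrides consumed by the classifier:
#   x=z     lexical x -> /z/ reading (exemplo, exame)
#   ss=morph  the <ss> slot is governed by a morphological spelling rule
#             (verb ending of 'disse'), violations -> IPG_1
# verb_past marks simple-past verb forms whose final semivowel /w/ is a
# morpheme and must be spelled <u>.

.DSW_TABLE <- "word_id|form|gloss|syllab|stress|verb_past|x_reads_z|slot_rules
1|muito|very|mui.to|1|0|0|
2|quando|when|quan.do|1|0|0|
3|disse|said|di.sse|1|0|0|ss=morph
4|também|also|tam.bém|2|0|0|
5|vez|time|vez|1|0|0|
6|cachorro|dog|ca.cho.rro|2|0|0|
7|conseguiu|got|con.se.guiu|3|1|0|
8|encontrou|found|en.con.trou|3|1|0|
9|gente|people|gen.te|1|0|0|
10|guerra|war|gue.rra|1|0|0|
11|exemplo|example|e.xem.plo|2|0|1|
12|ajuda|help|a.ju.da|2|0|0|
13|assim|so|a.ssim|2|0|0|
14|brincar|play|brin.car|2|0|0|
15|futebol|soccer|fu.te.bol|3|0|0|
16|menino|boy|me.ni.no|2|0|0|
17|animal|animal|a.ni.mal|3|0|0|
18|carro|car|ca.rro|1|0|0|
19|casa|house|ca.sa|1|0|0|
20|então|then|en.tão|2|0|0|
21|homem|man|ho.mem|1|0|0|
22|jeito|way|jei.to|1|0|0|
23|por isso|therefore|por i.sso|2|0|0|
24|viajar|travel|vi.a.jar|3|0|0|
25|a gente|us|a gen.te|2|0|0|
26|almoço|lunch|al.mo.ço|2|0|0|
27|assalto|assault|a.ssal.to|2|0|0|
28|borracha|rubber|bo.rra.cha|2|0|0|
29|bruxa|witch|bru.xa|1|0|0|
30|cabeça|head|ca.be.ça|2|0|0|
31|caiu|fell|ca.iu|2|1|0|
32|começou|started|co.me.çou|3|1|0|
33|de repente|suddenly|de re.pen.te|3|0|0|
34|em cima|above|em ci.ma|2|0|0|
35|embaixo|under|em.bai.xo|2|0|0|
36|enxergar|see|en.xer.gar|3|0|0|
37|escola|school|es.co.la|2|0|0|
38|faz|does|faz|1|0|0|
39|fazer|do|fa.zer|2|0|0|
40|fez|did|fez|1|0|0|
41|girafa|giraffe|gi.ra.fa|2|0|0|
42|ninguém|nobody|nin.guém|2|0|0|
43|pegue|take|pe.gue|1|0|0|
44|porque|because|por.que|2|0|0|
45|professora|teacher|pro.fe.sso.ra|3|0|0|
46|quente|hot|quen.te|1|0|0|
47|tenho|have|te.nho|1|0|0|
48|alguém|somebody|al.guém|2|0|0|
49|amanhã|tomorrow|a.ma.nhã|3|0|0|
50|árvore|tree|ár.vo.re|1|0|0|
51|certo|right|cer.to|1|0|0|
52|correr|run|co.rrer|2|0|0|
53|exame|test|e.xa.me|2|0|1|
54|feliz|happy|fe.liz|2|0|0|
55|presente|gift|pre.sen.te|2|0|0|
56|relógio|clock|re.ló.gio|2|0|0|
57|saudade|longing|sau.da.de|2|0|0|
58|tempo|time|tem.po|1|0|0|
59|tesoura|scissors|te.sou.ra|2|0|0|
60|galinha|chicken|ga.li.nha|2|0|0|"

# Words printed in the source study's fixed lexical 'others' list (invented or
# foreign forms that are not analyzed edit-by-edit).
.OTHER_FORMS <- c("almoção", "temum", "futball")

#' The 'Dyslexic Sight Words' dictation lexicon
#'
#' Returns the 60-entry target-word lexicon in list order (word_id 1-60), with
#' syllabification (over grapheme units), stress, part-of-speech flags, and
#' per-slot orthographic-rule overrides.
#'
#' @return A data frame of class `dsw_lexicon` with one row per target word:
#'   `word_id`, `form`, `gloss`, `syllab` (dot/space-delimited), `stress`
#'   (index of the stressed syllable), `multiword`, `verb_past`, `x_reads_z`,
#'   `slot_rules`, `n_syllables`. A `syllable_spans` attribute (list of
#'   per-word integer vectors mapping grapheme units to syllables) is attached.
#' @examples
#' lex <- dsw_lexicon()
#' lex[lex$word_id == 19, "form"]
#' @export
dsw_lexicon <- function() {
  df <- utils::read.delim(text = .DSW_TABLE, sep = "|", quote = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  df$form <- vapply(df$form, normalize_form, character(1), USE.NAMES = FALSE)
  df$verb_past <- df$verb_past == 1
  df$x_reads_z <- df$x_reads_z == 1
  df$slot_rules[is.na(df$slot_rules)] <- ""
  df$multiword <- grepl(" ", df$form)
  df$n_syllables <- vapply(strsplit(df$syllab, "[. ]"), length, integer(1))
  stopifnot(nrow(df) == 60L, identical(df$word_id, 1:60),
            all(df$stress >= 1 & df$stress <= df$n_syllables))
  attr(df, "syllable_spans") <- lapply(seq_len(nrow(df)), function(i) {
    syllable_map(df$form[i], df$syllab[i])
  })
  class(df) <- c("dsw_lexicon", class(df))
  df
}

# Map each grapheme unit of `form` to its syllable index, from the
# dot-delimited letter syllabification. Digraph units fall in the syllable
# where they start.
syllable_map <- function(form, syllab) {
  gs <- segment_graphemes(form)
  sylls <- strsplit(syllab, "[. ]")[[1]]
  # cumulative letter count at which each syllable ends (spaces excluded)
  ends <- cumsum(nchar(sylls))
  pos <- 0L
  out <- integer(length(gs$units))
  for (i in seq_along(gs$units)) {
    out[i] <- which(ends > pos)[1]
    pos <- pos + nchar(gs$units[i])
  }
  stopifnot(!anyNA(out), pos == sum(nchar(sylls)))
  out
}

#' Look up one lexicon entry
#'
#' @param word_id Integer 1-60, or a target form.
#' @param lexicon Optional pre-loaded lexicon (for repeated calls).
#' @return A one-row list with the entry's fields plus `syllable_of` (integer
#'   vector: syllable index of each grapheme unit) and `units`.
#' @export
dsw_entry <- function(word_id, lexicon = NULL) {
  lex <- if (is.null(lexicon)) dsw_lexicon() else lexicon
  if (is.character(word_id)) {
    idx <- match(normalize_form(word_id), lex$form)
  } else {
    idx <- match(as.integer(word_id), lex$word_id)
  }
  if (is.na(idx)) stop("lexicon_error: unknown target word: ", word_id)
  entry <- as.list(lex[idx, , drop = FALSE])
  entry$syllable_of <- attr(lex, "syllable_spans")[[idx]]
  entry$units <- segment_graphemes(entry$form)$units
  entry
}

#' Orthographic rules active at a grapheme slot
#'
#' Returns the positional, morphological, and lexical spelling rules whose
#' context matches a grapheme slot of a target word, ordered by specificity
#' (morphological > contextual > lexical). The classifier maps violations of
#' contextual/morphological rules to IPG_1 and lexical choices to IPG_2.
#'
#' @param gs A `grapheme_string` for the target form (or character scalar).
#' @param position Integer grapheme-unit index.
#' @param word_meta A lexicon entry from [dsw_entry()].
#' @return Data frame with columns `rule_id`, `rule_class`.
#' @examples
#' lookup_rules("tempo", 3, dsw_entry("tempo"))
#' @export
lookup_rules <- function(gs, position, word_meta) {
  if (is.character(gs)) gs <- segment_graphemes(normalize_form(gs))
  units <- gs$units
  if (position < 1 || position > length(units)) stop("invalid position")
  g <- units[position]
  nxt <- if (position < length(units)) units[position + 1L] else ""
  prev <- if (position > 1L) units[position - 1L] else ""
  final <- position == length(units)
  rules <- list()
  add <- function(id, cls) rules[[length(rules) + 1L]] <<- list(rule_id = id, rule_class = cls)

  # per-word slot overrides from the lexicon
  slot <- word_meta$slot_rules
  if (nzchar(slot)) {
    for (kv in strsplit(slot, ";", fixed = TRUE)[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (parts[1] == g && parts[2] == "morph") add(paste0("morph-", g), "morphological")
    }
  }
  # morphological: past-tense semivowel <u>
  if (final && isTRUE(word_meta$verb_past) && g %in% c("u", "l", "o")) {
    add("past-tense-semivowel", "morphological")
  }
  # contextual rules
  if (g %in% c("m", "n") && !is_vowel_unit(nxt) && !final) {
    add(if (base_vowel(nxt) %in% c("p", "b") || nxt %in% c("p", "b"))
          "nasal-before-p/b" else "nasal-coda-internal", "contextual")
  }
  if (g %in% c("qu", "gu") && base_vowel(nxt) %in% c("e", "i")) {
    add("digraph-qu/gu-before-e,i", "contextual")
  }
  if (g == "rr") add("intervocalic-rr", "contextual")
  if (g %in% .TILDE_VOWELS) add("tilde-nasalization", "contextual")
  if (final && g %in% c("e", "o") &&
      word_meta$n_syllables - word_meta$stress == 1L) {
    add("final-posttonic-vowel", "contextual")
  }
  if (g == "x" && (grepl("^en", word_meta$form) ||
                   (is_vowel_unit(prev) && position > 2L &&
                    is_vowel_unit(units[position - 2L])))) {
    add("x-after-en/diphthong", "contextual")
  }
  # lexical (arbitrary) choices
  if (g %in% c("g", "j") && base_vowel(nxt) %in% c("e", "i")) {
    add("g/j-before-e,i", "lexical")
  }
  if (g %in% c("s", "ss", "ç", "c", "sc", "sç", "xc", "xs", "z", "x")) {
    add("sibilant-choice", "lexical")
  }
  if (final && g %in% c("l", "u", "o") && !isTRUE(word_meta$verb_past)) {
    add("final-semivowel-l/u/o", "lexical")
  }
  if (g %in% c("m", "n") && final) add("final-nasal-m/n", "lexical")
  if (g %in% c("e", "i", "o", "u") && !final &&
      word_meta$syllable_of[position] < word_meta$stress) {
    add("pretonic-vowel", "lexical")
  }
  if (length(rules) == 0) return(data.frame(rule_id = character(0),
                                            rule_class = character(0)))
  out <- do.call(rbind, lapply(rules, as.data.frame))
  ord <- order(match(out$rule_class, c("morphological", "contextual", "lexical")))
  out[ord, , drop = FALSE]
}

#' Fixed list of lexical 'others' forms
#'
#' Written productions that the taxonomy treats as OTHER by lexical listing
#' (another real word, a foreign spelling, an invented word), rather than by
#' edit analysis.
#' @return Character vector.
#' @export
other_form_list <- function() .OTHER_FORMS
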