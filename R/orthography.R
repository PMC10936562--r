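# Brazilian Portuguese grapheme inventory, normalization, segmentation and a
# reading-direction (grapheme-to-phoneme) rule layer sufficient to decide
# whether two spellings of a dictation target sound the same.

# Digraphs treated as single functional units. qu/gu count as digraphs only
# before a vowel (in "aguda" the <u> is the nucleus, not part of a digraph);
# sc/sc-cedilla/xc/xs only before e/i (in "escola" <sc> spells /sk/, two units).
.DIGRAPHS_ALWAYS <- c("rr", "ss", "ch", "lh", "nh")
.DIGRAPHS_PREVOWEL <- c("qu", "gu")
.DIGRAPHS_PRE_EI <- c("sc", "sç", "xc", "xs")
.VOWELS <- c("a", "e", "i", "o", "u",
             "á", "é", "í", "ó", "ú",   # acute
             "â", "ê", "ô",                        # circumflex
             "à", "ã", "õ")                        # grave, tilde
.ACUTE_CIRC <- c("á", "é", "í", "ó", "ú",
                 "â", "ê", "ô", "à")
.TILDE_VOWELS <- c("ã", "õ")
.ALPHABET <- c(letters, "ç", .VOWELS)

#' Normalize a written dictation form
#'
#' Lowercases, composes to Unicode NFC, strips leading/trailing whitespace and
#' collapses internal whitespace runs to a single space.
#'
#' @param raw Character scalar, the raw written form.
#' @return Normalized character scalar.
#' @examples
#' normalize_form("Derepente ")
#' normalize_form("em  baixo")
#' @export
normalize_form <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) {
    stop("invalid_response: written form must be a single non-NA string")
  }
  x <- enc2utf8(as.character(raw))
  x <- stringi_nfc(x)
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- sub("^ ", "", sub(" $", "", x))
  if (!nzchar(x)) {
    stop("invalid_response: blank written form")
  }
  x
}

# NFC composition without external dependencies: compose the combining
# diacritics that occur in dictation data (acute, grave, circumflex, tilde,
# cedilla) onto their base letters. Idempotent on already-composed input.
stringi_nfc <- function(x) {
  comb <- c(acute = "́", grave = "̀", circ = "̂",
            tilde = "̃", cedil = "̧")
  compose <- list(
    c("á", "á"), c("é", "é"), c("í", "í"),
    c("ó", "ó"), c("ú", "ú"),
    c("à", "à"),
    c("â", "â"), c("ê", "ê"), c("ô", "ô"),
    c("ã", "ã"), c("õ", "õ"),
    c("ç", "ç"),
    c("Á", "Á"), c("É", "É"), c("Í", "Í"),
    c("Ó", "Ó"), c("Ú", "Ú"),
    c("Â", "Â"), c("Ê", "Ê"), c("Ô", "Ô"),
    c("Ã", "Ã"), c("Õ", "Õ"), c("Ç", "Ç")
  )
  for (p in compose) x <- gsub(p[1], p[2], x, fixed = TRUE)
  x
}

#' Segment a normalized form into grapheme units
#'
#' Left-to-right maximal-munch tokenization against the digraph inventory.
#' Digraphs (rr, ss, ch, lh, nh; qu/gu before a vowel; sc, s-cedilla-c, xc, xs
#' before e/i) become single units. Token boundaries (spaces) are recorded as
#' boundary positions, not units.
#'
#' @param form Normalized character scalar (see [normalize_form()]).
#' @return Object of class `grapheme_string`: list with `units` (character
#'   vector of unit surfaces), `kind` (`"simple"`/`"digraph"`), `boundaries`
#'   (integer positions: a boundary after unit i is recorded as i), and `form`.
#' @examples
#' segment_graphemes("cachorro")$units
#' segment_graphemes("por isso")
#' @export
segment_graphemes <- function(form) {
  chars <- strsplit(form, "", fixed = FALSE)[[1]]
  bad <- setdiff(chars, c(.ALPHABET, " "))
  if (length(bad) > 0) {
    stop("non_alphabetic: characters outside the Portuguese alphabet: ",
         paste(unique(bad), collapse = " "))
  }
  units <- character(0)
  boundaries <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == " ") {
      boundaries <- c(boundaries, length(units))
      i <- i + 1L
      next
    }
    pair <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    nxt2 <- if (i + 2L <= n) chars[i + 2L] else ""
    take2 <- FALSE
    if (pair %in% .DIGRAPHS_ALWAYS) take2 <- TRUE
    if (pair %in% .DIGRAPHS_PREVOWEL && nxt2 %in% .VOWELS) take2 <- TRUE
    if (pair %in% .DIGRAPHS_PRE_EI && base_vowel(nxt2) %in% c("e", "i")) take2 <- TRUE
    if (take2) {
      units <- c(units, pair)
      i <- i + 2L
    } else {
      units <- c(units, ch)
      i <- i + 1L
    }
  }
  structure(list(units = units,
                 kind = ifelse(nchar(units) == 2L, "digraph", "simple"),
                 boundaries = boundaries,
                 form = form),
            class = "grapheme_string")
}

#' @export
print.grapheme_string <- function(x, ...) {
  u <- x$units
  if (length(x$boundaries)) {
    for (b in rev(x$boundaries)) u <- append(u, "|", after = b)
  }
  cat("<grapheme_string> [", paste(u, collapse = ","), "]\n", sep = "")
  invisible(x)
}

# Strip acute/circumflex/grave (stress or timbre marks); tilde and cedilla are
# phonemic and kept.
strip_accent <- function(g) {
  map <- c("á" = "a", "é" = "e", "í" = "i", "ó" = "o",
           "ú" = "u", "â" = "a", "ê" = "e", "ô" = "o",
           "à" = "a")
  out <- unname(map[g])
  out[is.na(out)] <- g[is.na(out)]
  out
}

# Base letter of a vowel with any diacritic removed (tilde included).
base_vowel <- function(g) {
  map <- c("á" = "a", "é" = "e", "í" = "i", "ó" = "o",
           "ú" = "u", "â" = "a", "ê" = "e", "ô" = "o",
           "à" = "a", "ã" = "a", "õ" = "o")
  out <- unname(map[g])
  out[is.na(out)] <- g[is.na(out)]
  out
}

is_vowel_unit <- function(g) g %in% .VOWELS
accent_only_pair <- function(a, b) {
  a != b && strip_accent(a) == strip_accent(b) &&
    !(a %in% .TILDE_VOWELS) && !(b %in% .TILDE_VOWELS)
}

# Phonemes of one grapheme unit in context (reading direction).
# `units` character vector for ONE token (no boundaries), `i` the unit index,
# `x_sound` optional override for <x> ("z" in exemplo/exame).
unit_phones <- function(units, i, x_sound = NULL) {
  g <- units[i]
  n <- length(units)
  prev <- if (i > 1L) units[i - 1L] else ""
  nxt <- if (i < n) units[i + 1L] else ""
  nxt_base <- base_vowel(nxt)
  final <- i == n
  initial <- i == 1L

  if (g %in% c("h")) return(character(0))
  if (g == "nh") return("J")   # palatal nasal
  if (g == "lh") return("L")   # palatal lateral
  if (g == "ch") return("x")   # /S/ as in 'sh' -> symbol "x"
  if (g %in% c("ss", "sc", "sç", "xc", "xs")) return("s")
  if (g == "ç") return("s")
  if (g == "rr") return("R")
  if (g == "c") return(if (nxt_base %in% c("e", "i")) "s" else "k")
  if (g == "qu") return(if (nxt_base %in% c("e", "i")) "k" else c("k", "w"))
  if (g == "gu") return(if (nxt_base %in% c("e", "i")) "g" else c("g", "w"))
  if (g == "g") return(if (nxt_base %in% c("e", "i")) "Z" else "g")
  if (g == "j") return("Z")
  if (g == "x") {
    if (!is.null(x_sound) && identical(x_sound, "z")) return("z")
    return("x")
  }
  if (g == "q") return("k")
  if (g == "s") {
    if (final) return("S")
    if (is_vowel_unit(prev) && is_vowel_unit(nxt)) return("z")
    return("s")
  }
  if (g == "z") return(if (final) "S" else "z")
  if (g == "r") {
    if (initial) return("R")
    if (prev %in% c("n", "l", "s")) return("R")
    return("r")
  }
  if (g %in% c("m", "n")) {
    if (final || !is_vowel_unit(nxt)) return("N")
    return(g)
  }
  if (g == "l") {
    if (final || !is_vowel_unit(nxt)) return("w")
    return("l")
  }
  if (g %in% .TILDE_VOWELS) {
    return(c(base_vowel(g), "N"))
  }
  if (is_vowel_unit(g)) {
    bg <- base_vowel(g)
    accented <- g %in% .ACUTE_CIRC
    # falling diphthong glides
    if (bg == "i" && is_vowel_unit(prev) && base_vowel(prev) != "i" && !accented) {
      return("y")
    }
    if (bg == "u" && is_vowel_unit(prev) && base_vowel(prev) != "u" && !accented) {
      return("w")
    }
    # word-final post-vocalic o is a glide too (falling diphthong: -io, -ao)
    if (bg == "o" && final && is_vowel_unit(prev) && base_vowel(prev) != "o" &&
        !accented) {
      return("w")
    }
    # final unstressed vowel raising (Brazilian Portuguese)
    if (final && !accented) {
      if (bg == "e") return("i")
      if (bg == "o") return("u")
    }
    return(bg)
  }
  g   # p b t d f v k ...
}

#' Grapheme-to-phoneme conversion (broad transcription)
#'
#' Applies the Brazilian Portuguese reading-direction rule table: c -> /s/
#' before e,i else /k/; cedilla -> /s/; g -> /Z/ before e,i else /g/; qu,gu ->
#' /k/,/g/ before e,i (else /kw/,/gw/); intervocalic s -> /z/; rr and
#' word-initial r -> /R/; ch and default x -> /S/ with per-word lexical
#' overrides (x -> /z/ in "exemplo", "exame"); coda m/n and tilde -> nasal
#' archiphoneme /N/; token-final s,z -> archiphoneme /S/; final unstressed
#' e -> /i/, o -> /u/; initial h silent. Token boundaries in multiword forms
#' are ignored in the output (phonological joining).
#'
#' @param gs A `grapheme_string` (or a character scalar, normalized first).
#' @param word_meta Optional `TargetWord` metadata (a row of [dsw_lexicon()]);
#'   supplies the lexical x-sound override.
#' @return Character vector of phoneme codes (class `phoneme_string`).
#'   Symbols: vowels a e i o u, glides y w, N and S archiphonemes,
#'   x = voiceless postalveolar fricative, Z = voiced counterpart,
#'   J/L palatal nasal/lateral, R strong rhotic, r flap, plus plain stops.
#' @examples
#' g2p("casa")
#' g2p("vez")
#' @export
g2p <- function(gs, word_meta = NULL) {
  if (is.character(gs)) gs <- segment_graphemes(normalize_form(gs))
  x_sound <- NULL
  if (!is.null(word_meta) && isTRUE(word_meta$x_reads_z)) x_sound <- "z"
  toks <- split_tokens(gs)
  out <- character(0)
  for (tok in toks) {
    for (i in seq_along(tok)) out <- c(out, unit_phones(tok, i, x_sound))
  }
  structure(out, class = "phoneme_string")
}

#' @export
print.phoneme_string <- function(x, ...) {
  cat("/", paste(unclass(x), collapse = ","), "/\n", sep = "")
  invisible(x)
}

# Split a grapheme_string into a list of per-token unit vectors.
split_tokens <- function(gs) {
  if (length(gs$boundaries) == 0) return(list(gs$units))
  cuts <- c(0L, sort(gs$boundaries), length(gs$units))
  lapply(seq_len(length(cuts) - 1L),
         function(k) gs$units[(cuts[k] + 1L):cuts[k + 1L]])
}

#' Phonological equivalence of two written forms
#'
#' TRUE iff both forms read identically under the grapheme-to-phoneme rule
#' table, with per-word lexical overrides applied to the first (target) form's
#' slots. Token boundaries are ignored (a hyposegmented form can still be
#' sound-preserving).
#'
#' @param a,b Written forms (raw text; normalized internally).
#' @param word_meta Optional lexicon row supplying lexical overrides for `a`.
#' @return Logical flag.
#' @examples
#' phonologically_equivalent("a gente", "agenti")
#' phonologically_equivalent("começou", "comeco")
#' @export
phonologically_equivalent <- function(a, b, word_meta = NULL) {
  pa <- g2p(segment_graphemes(normalize_form(a)), word_meta)
  pb <- g2p(segment_graphemes(normalize_form(b)), word_meta)
  length(pa) == length(pb) && all(unclass(pa) == unclass(pb))
}
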