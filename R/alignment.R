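# Grapheme-level alignment between a target and a produced form. Works on
# grapheme units (digraphs are single units, so gu -> g is one substitution),
# with adjacent transpositions (optimal-string-alignment recurrence) and a
# substitution cost that favours sound-preserving pairings.

.SUB_COST_EQUIV <- 0.5   # phonologically equivalent in context, or accent-only

# TRUE when the vowel at position i is nasalized by a following coda m/n.
coda_nasal_after <- function(units, i) {
  if (i >= length(units)) return(FALSE)
  nxt <- units[i + 1L]
  nxt %in% c("m", "n") &&
    (i + 1L == length(units) || !is_vowel_unit(units[i + 2L]))
}

# Cost of substituting target unit i by response unit j, in context. Two
# vowels only count as equivalent if their nasal context agrees (final /u/ in
# "tenho" is not the nasal /uN/ of "temum").
sub_cost <- function(tu, i, ru, j, x_sound = NULL) {
  a <- tu[i]; b <- ru[j]
  if (a == b) return(0)
  if (accent_only_pair(a, b)) return(.SUB_COST_EQUIV)
  # same base letter under any diacritic (tilde included): close spellings
  if (is_vowel_unit(a) && is_vowel_unit(b) && base_vowel(a) == base_vowel(b)) {
    return(.SUB_COST_EQUIV)
  }
  pa <- unit_phones(tu, i, x_sound)
  pb <- unit_phones(ru, j, NULL)
  if (length(pa) == length(pb) && all(pa == pb)) {
    if (is_vowel_unit(a) && is_vowel_unit(b) &&
        coda_nasal_after(tu, i) != coda_nasal_after(ru, j)) {
      return(1)
    }
    return(.SUB_COST_EQUIV)
  }
  # near-equivalent spelling families: sibilant /s z S/ choices, c/qu for /k/,
  # and digraph simplification/inflation (gu/g, qu/q, rr/r)
  sib <- c("s", "z", "S")
  if (all(pa %in% sib) && all(pb %in% sib)) return(.SUB_COST_EQUIV)
  if ((a == "c" && b == "qu") || (a == "qu" && b == "c")) return(.SUB_COST_EQUIV)
  pair <- c(a, b)
  if (setequal(pair, c("gu", "g")) || setequal(pair, c("qu", "q")) ||
      setequal(pair, c("rr", "r"))) {
    return(.SUB_COST_EQUIV)
  }
  1
}

#' Align two grapheme strings
#'
#' Minimal-cost edit script between target and response grapheme-unit
#' sequences under costs: match 0, substitution 1 (0.5 when the two units are
#' phonologically equivalent in context, which biases the alignment toward
#' sound-preserving pairings), insertion/deletion 1, adjacent transposition 1.
#' Ties prefer substitution over an insertion+deletion pair, then the leftmost
#' placement. Token boundaries are ignored here; see [boundary_diff()].
#'
#' @param target,response `grapheme_string` objects (or character scalars,
#'   normalized and segmented internally).
#' @param word_meta Optional lexicon entry for the target (lexical x-sound).
#' @return An `edit_script`: data frame of ops (`kind`, `t_from`, `t_to`,
#'   `r_from`, `r_to`, `t_sur`, `r_sur`) with a `cost` attribute.
#' @examples
#' align_graphemes("embaixo", "ebaixo")
#' align_graphemes("porque", "proque")
#' @export
align_graphemes <- function(target, response, word_meta = NULL) {
  if (is.character(target)) target <- segment_graphemes(normalize_form(target))
  if (is.character(response)) response <- segment_graphemes(normalize_form(response))
  tu <- target$units
  ru <- response$units
  x_sound <- if (!is.null(word_meta) && isTRUE(word_meta$x_reads_z)) "z" else NULL
  n <- length(tu); m <- length(ru)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- sub_cost(tu, i, ru, j, x_sound)
      best <- min(D[i, j] + sc, D[i, j + 1L] + 1, D[i + 1L, j] + 1)
      if (i > 1L && j > 1L && tu[i - 1L] == ru[j] && tu[i] == ru[j - 1L] &&
          tu[i] != tu[i - 1L]) {
        best <- min(best, D[i - 1L, j - 1L] + 1)
      }
      D[i + 1L, j + 1L] <- best
    }
  }
  # backtrace (ops accumulated in preallocated vectors, reversed at the end)
  cap <- n + m + 2L
  v_kind <- character(cap); v_tf <- integer(cap); v_tt <- integer(cap)
  v_rf <- integer(cap); v_rt <- integer(cap)
  np <- 0L
  push <- function(kind, tf, tt, rf, rt) {
    np <<- np + 1L
    v_kind[np] <<- kind; v_tf[np] <<- tf; v_tt[np] <<- tt
    v_rf[np] <<- rf; v_rt[np] <<- rt
  }
  i <- n; j <- m
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (i > 1L && j > 1L && tu[i - 1L] == ru[j] && tu[i] == ru[j - 1L] &&
        tu[i] != tu[i - 1L] &&
        abs(D[i + 1L, j + 1L] - (D[i - 1L, j - 1L] + 1)) < eps) {
      push("transposition", i - 1L, i, j - 1L, j)
      i <- i - 2L; j <- j - 2L
    } else if (i > 0L && abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + 1)) < eps &&
               (j == 0L ||
                D[i, j] + sub_cost(tu, i, ru, j, x_sound) >
                D[i, j + 1L] + 1 - eps)) {
      # a deletion on the optimal path; taking it here lets trailing
      # transpositions surface (substitution still beats indel pairs on cost)
      push("deletion", i, i, j + 1L, j)
      i <- i - 1L
    } else if (i > 0L && j > 0L &&
               abs(D[i + 1L, j + 1L] -
                   (D[i, j] + sub_cost(tu, i, ru, j, x_sound))) < eps) {
      push(if (tu[i] == ru[j]) "match" else "substitution", i, i, j, j)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + 1)) < eps) {
      push("deletion", i, i, j + 1L, j)
      i <- i - 1L
    } else {
      push("insertion", i + 1L, i, j, j)
      j <- j - 1L
    }
  }
  idx <- rev(seq_len(np))
  tf <- v_tf[idx]; tt <- v_tt[idx]; rf <- v_rf[idx]; rt <- v_rt[idx]
  surf <- function(u, from, to) {
    vapply(seq_along(from), function(q) {
      if (to[q] >= from[q]) paste(u[from[q]:to[q]], collapse = "") else ""
    }, character(1))
  }
  ops <- data.frame(kind = v_kind[idx], t_from = tf, t_to = tt,
                    r_from = rf, r_to = rt,
                    t_sur = surf(tu, tf, tt), r_sur = surf(ru, rf, rt),
                    stringsAsFactors = FALSE)
  structure(ops, cost = D[n + 1L, m + 1L], target = tu, response = ru,
            class = c("edit_script", "data.frame"))
}

#' @export
print.edit_script <- function(x, ...) {
  cat("<edit_script> cost =", attr(x, "cost"), "\n")
  cat(" ", edit_notation(x), "\n")
  invisible(x)
}

#' Compact text notation for an edit script
#'
#' `M` match, `S(a>b)` substitution, `D(a)` deletion, `I(b)` insertion,
#' `T(ab)` adjacent transposition, `J` join, `P` split.
#' @param script An `edit_script` or list of boundary ops.
#' @return Character scalar.
#' @export
edit_notation <- function(script) {
  code <- vapply(seq_len(nrow(script)), function(k) {
    op <- script[k, ]
    switch(op$kind,
           match = "M",
           substitution = sprintf("S(%s>%s)", op$t_sur, op$r_sur),
           deletion = sprintf("D(%s)", op$t_sur),
           insertion = sprintf("I(%s)", op$r_sur),
           transposition = sprintf("T(%s)", op$t_sur),
           join = "J", split = "P", "?")
  }, character(1))
  paste(code, collapse = " ")
}

#' Apply an edit script to its target
#'
#' Reconstructs the response unit sequence from the target and the script;
#' used as the script-application invariant in tests.
#' @param script An `edit_script`.
#' @return Character vector of response units.
#' @export
apply_edit_script <- function(script) {
  out <- character(0)
  for (k in seq_len(nrow(script))) {
    op <- script[k, ]
    out <- c(out, switch(op$kind,
                         match = op$t_sur,
                         substitution = op$r_sur,
                         insertion = op$r_sur,
                         deletion = character(0),
                         transposition = {
                           u <- attr(script, "target")[op$t_from:op$t_to]
                           rev(u)
                         }))
  }
  # re-segment: concatenating units can fuse into digraphs (e.g. r+r -> rr)
  segment_graphemes(paste(out, collapse = ""))$units
}

#' Token-boundary differences (hypo/hypersegmentation)
#'
#' Emits a `join` op for every target token boundary absent from the response
#' (hyposegmentation: "de repente" -> "derepente") and a `split` op for every
#' response boundary inside a target token (hypersegmentation: "embaixo" ->
#' "em baixo"). Boundary correspondence is established through the grapheme
#' alignment of the space-free forms.
#'
#' @param target,response `grapheme_string` objects or character scalars.
#' @param word_meta Optional lexicon entry for the target.
#' @param script Optional precomputed [align_graphemes()] script (avoids
#'   re-aligning).
#' @return Data frame of ops (possibly 0-row) with `kind` in join/split.
#' @examples
#' boundary_diff("de repente", "derepente")
#' boundary_diff("embaixo", "em baixo")
#' @export
boundary_diff <- function(target, response, word_meta = NULL, script = NULL) {
  if (is.character(target)) target <- segment_graphemes(normalize_form(target))
  if (is.character(response)) response <- segment_graphemes(normalize_form(response))
  if (is.null(script)) script <- align_graphemes(target, response, word_meta)
  # map: after target unit i the aligned response position
  t2r <- integer(length(target$units))
  pos_r <- 0L
  kinds <- script$kind; tfv <- script$t_from; ttv <- script$t_to
  rtv <- script$r_to
  for (k in seq_along(kinds)) {
    if (kinds[k] %in% c("match", "substitution", "transposition", "deletion")) {
      if (kinds[k] != "deletion") pos_r <- rtv[k]
      t2r[tfv[k]:max(tfv[k], ttv[k])] <- pos_r
    } else {
      pos_r <- rtv[k]
    }
  }
  ops <- list()
  for (b in target$boundaries) {
    rb <- if (b == 0L) 0L else t2r[b]
    if (!(rb %in% response$boundaries)) {
      ops[[length(ops) + 1L]] <- data.frame(kind = "join", t_from = b,
                                            t_to = b, r_from = rb, r_to = rb,
                                            t_sur = "", r_sur = "",
                                            stringsAsFactors = FALSE)
    }
  }
  mapped_t_boundaries <- vapply(target$boundaries,
                                function(b) if (b == 0L) 0L else t2r[b],
                                integer(1))
  for (b in response$boundaries) {
    if (!(b %in% mapped_t_boundaries)) {
      ops[[length(ops) + 1L]] <- data.frame(kind = "split", t_from = NA_integer_,
                                            t_to = NA_integer_, r_from = b,
                                            r_to = b, t_sur = "", r_sur = "",
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(ops) == 0) {
    return(data.frame(kind = character(0), t_from = integer(0),
                      t_to = integer(0), r_from = integer(0),
                      r_to = integer(0), t_sur = character(0),
                      r_sur = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, ops)
}

#' Grapheme similarity between target and response
#'
#' `1 - cost / max(unit lengths)`, clamped to `[0, 1]`, computed on the
#' space-free grapheme alignment. Gatekeeper for the OTHER category.
#'
#' @inheritParams align_graphemes
#' @return Number in `[0, 1]`.
#' @examples
#' grapheme_similarity("casa", "casa")
#' grapheme_similarity("tenho", "temum")
#' @export
grapheme_similarity <- function(target, response, word_meta = NULL) {
  if (is.character(target)) target <- segment_graphemes(normalize_form(target))
  if (is.character(response)) response <- segment_graphemes(normalize_form(response))
  script <- align_graphemes(target, response, word_meta)
  mx <- max(length(target$units), length(response$units))
  if (mx == 0) return(1)
  max(0, min(1, 1 - attr(script, "cost") / mx))
}
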