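---
title: "Semiological classification of Brazilian Portuguese spelling errors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiological classification of Brazilian Portuguese spelling errors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiospell)
```

## The problem and the model

Dictation tasks are a standard probe of spelling development and of
dysorthography in developmental dyslexia. A raw correct/incorrect score
hides the structure of the errors: writing *começou* as `comeco` (the
cedilla is lost and the reading changes) reflects a different underlying
process than writing it as `comessou` (the reading is preserved but the
wrong sibilant spelling was chosen). The semiological taxonomy distinguishes
**natural spelling** errors — tied to phoneme-level processing: RPG
(reading-changing substitutions), OIL (letter omissions/insertions), ASS
(syllable-structure alterations), USW (unconventional word segmentation) —
from **arbitrary spelling** errors — tied to the orthographic lexicon: IPG_1
(violations of context- or morphology-dependent rules), IPG_2 (failures of
lexically arbitrary choices), AAW (accentuation alterations).

This package turns that expert taxonomy into a deterministic classifier for
the 60-word 'Dyslexic Sight Words' (DSW) dictation list, plus the
group-comparison statistics and a synthetic corpus generator, so the whole
analysis chain is reproducible and testable.

## Orthographic layer

Responses are lowercased, NFC-composed, and whitespace-normalized.
Segmentation is a left-to-right maximal munch against the digraph inventory
(`rr ss ch lh nh`, plus `qu gu` before a vowel and `sc sç xc xs` before
e/i), so digraph simplification (`gu`→`g`) is a single substitution, as the
taxonomy treats it.

The grapheme-to-phoneme layer is a broad-transcription reading rule table:
`c`→/s/ before e,i else /k/; `ç`→/s/; `g`→/ʒ/ before e,i else /g/;
`qu`,`gu`→/k/,/g/ before e,i (else /kw/, /gw/); intervocalic `s`→/z/; `rr`
and word-initial `r` strong rhotic; `ch` and default `x`→/ʃ/ with per-word
lexical overrides (`x`→/z/ in *exemplo*, *exame*); coda `m`/`n` and the
tilde map to the nasal archiphoneme /N/; token-final `s`,`z` to the coda
archiphoneme /S/; final unstressed `e`→/i/ and `o`→/u/ (Brazilian vowel
raising — required so `genti`, `sertu`, `muitu` count as sound-preserving);
word-initial `h` is silent. The dialect choices are forced by the gold
labels: the tilde is a nasalization marker (its loss is IPG_1, not AAW),
while the cedilla is part of the grapheme `ç` (its loss changes the phoneme,
hence RPG).

Two details are worth flagging. First, one grapheme can lawfully emit two
phonemes (`ã` → /a/+/N/, `qu`+`a` → /k/+/w/), so the invariant we test is
that every non-silent unit contributes *at least one* phoneme and `h`
contributes none — not an exact length match. Second, syllabification and
stress are hand-encoded per lexicon entry rather than computed: no
syllabifier is needed for 60 words, and responses inherit the target's
metadata through the alignment. (The conventional syllabification is stored
even where one could argue about cluster analysis, e.g. *a-ssal-to*.)

## Alignment

Target and response are aligned at the grapheme-unit level with the
optimal-string-alignment recurrence: match 0, substitution 1, insertion and
deletion 1, adjacent transposition 1. A substitution costs 0.5 when the two
units are phonologically equivalent in context, when they differ only by a
diacritic, or when they belong to a near-equivalent spelling family
(sibilant /s z S/ spellings; `c`/`qu`; digraph simplification pairs). The
0.5 bias makes sound-preserving pairings out-compete insertion–deletion
pairs, which is what keeps alignments interpretable (e.g. `ausato` for
*assalto* aligns as a migrated semivowel plus a sibilant substitution, not
as an arbitrary letter salad). Vowel equivalence additionally requires the
nasal context to agree on both sides, which is what pushes `temum` (for
*tenho*) below the OTHER gate.

Ties prefer substitutions over indel pairs (guaranteed by the cost design)
and let trailing deletions surface before the diagonal so that
transpositions at the word end are found (`encontor` = transposition +
omission). Transpositions are restricted to adjacent units; longer-range
moves (the migrated /w/ of `alçato`) are recognized by the classifier as a
deletion/insertion pair of the same grapheme — or of two /w/ spellings or
two sibilant spellings — in different syllables.

Similarity is `1 − cost/max(lengths)`. Forms below 0.5 become OTHER; the
threshold is a config knob whose default is fixed by two constraints: the
gold `temum` must fail it and every categorized gold form must pass it.

## The classifier: a precedent cascade

The decision cascade is: (1) equality → correct; (2) OTHER gate (blank,
non-letters, low similarity, or the small lexical OTHER list `almoção`,
`temum`, `futball`); (3) every boundary join/split → USW; (4)
acute/circumflex-only differences → AAW; (5) every remaining edit is labeled
by a precedent table reconstructed from the gold analyses. The key
precedents, each anchored in a gold judgment:

* sibilant-family substitutions where both spellings read /s z S/ → IPG_2
  (`asim`, `almoso`, `cabessa`), except slots governed by a morphological
  rule, e.g. the `ss` of *disse* → IPG_1 (`dice`);
* digraph simplification `gu`→`g`, `qu`→`q`, and `rr`↔`r` → IPG_1 even when
  the naive reading changes (`consegiu`, `guera`, `girrafa`); `c`→`qu` →
  IPG_1; `qu`→`c`+`u` → IPG_2 (`cuado`);
* `x`↔`ch` for /ʃ/: contextual (IPG_1) after word-initial `en` or a
  diphthong (`enchergar`, `embaicho`), lexical (IPG_2) elsewhere (`brucha`,
  `caxoro`);
* `g`/`j` before e,i → IPG_2 (`geito`, `jente`); `j`→`g` elsewhere → IPG_1
  (`viagar`, `aguda`), following the gold labels despite the sound change;
* nasal codas: wrong letter before a consonant → IPG_1 (`tenpo`,
  `emcontrou`); word-final `m`↔`n` or a final nasal written as an oral
  vowel → IPG_2 (`homen`, `tabei`); onset/intervocalic nasal swaps → RPG
  (`encina`);
* final posttonic `e`↔`i` / `o`↔`u`: IPG_1 in paroxytones (`genti`,
  `sertu`), IPG_2 otherwise (`avori`); pretonic swaps → IPG_2 (`isami`,
  `minino`);
* the final semivowel /w/: morphologically fixed `u` in past-tense verbs →
  IPG_1 (`caio`, `encontrol`); lexically free `l`/`u`/`o` elsewhere → IPG_2
  (`animao`, `futibou`);
* tilde loss (with or without a compensating nasal letter) → IPG_1;
  acute/circumflex changes → AAW; cedilla loss before a/o/u → RPG;
* word-initial silent-`h` omission → IPG_2 (`omem`); all other single
  indels → OIL;
* ASS: adjacent transpositions (`proque`), grapheme migration across
  syllables (`alçato`, `assatou`), and anagram restructuring — identical
  letters (diacritics stripped) in a different order (`amahan`).

Unmatched substitutions fall through to phonological equivalence: a
sound-preserving edit takes IPG_1 when a contextual/morphological rule
governs the slot and IPG_2 otherwise; a sound-changing edit is RPG. The
whole function is pure: identical inputs and configuration give identical
labels, and multi-labeling is native (`dezora` carries RPG + OIL + IPG_2).

Where the gold annotations conflict internally — the same final-nasal swap
labeled IPG_1 for *assim* but IPG_2 for *homem*; the `l`/`u` choice of
*saudade* labeled rule-dependent while being described as an irregularity;
`çaudade`; the bundled multi-edit example `ezenpo` — the fixture records the
printed label with an `ambiguous` flag, and those records are excluded from
the benchmark subset. On that unambiguous subset the classifier contains
better than 98% of the printed labels; the residual misses are places where
the source text labels one instance of a pattern differently from its own
general rule (pretonic `e`→`i` in `direpente` called RPG, the omission
bundled into `gando`).

## Statistical layer

Per-word 2×2 tables (group × correct/incorrect) use the documented selection
rule: chi-square is inadmissible when more than 20% of cells have expected
frequency below 5, in which case the two-sided Fisher exact test
(probability-mass method) is used. Chi-square is Pearson without continuity
correction by default (a `yates` switch exists); the five per-word p-values
that can be checked against printed values are all Fisher-routed and
reproduce at 3 decimals. Mann–Whitney is two-sided, exact for untied
samples with n₁+n₂ ≤ 20 and a tie-corrected, continuity-corrected normal
approximation otherwise. The normality check is Lilliefors (parameters
estimated from the data) with a plain-KS switch, since the bare name
"Kolmogorov–Smirnov" on data-estimated parameters is only well calibrated
in the Lilliefors form.

Report rounding mirrors the source conventions: means half-up to 1 decimal,
shares half-up to 2, p-values to 3, and the mean-as-percentage-of-60
conversion is *truncated* to 2 decimals (28.3/60 → 47.16). One printed mean
(93/4 → 23.2) is inconsistent with any of these conventions and is excluded
from exact-match checks.

## Synthetic corpora

The generator's defaults are the study conditions: 10/8/4/8 students per
grade in each group, word-error rates 0.4716 (GD) and 0.0716 (GWD), and a
category mix proportional to the distinct-error-form counts per group (GD:
IPG_1 124, IPG_2 91, OIL 80, RPG 60, USW 24, AAW 13, ASS 7; GWD: 17, 12, 7,
4, 7, 4, 0, plus one OTHER). A second operator is applied to 10% of
misspelled words — a realism choice, since many gold forms carry two or
three simultaneous errors; the value is a profile field, not a printed
parameter.

Each category has a structural corruption operator (homorganic swaps for
RPG; single-unit indels for OIL; transpositions for ASS; boundary edits for
USW; licensed-alternative substitutions for IPG_1/IPG_2; accent stripping
for AAW; the lexical list for OTHER), constrained to candidates whose single
edit actually carries the intended label under the package's own rule table
— the operators are *defined by* the taxonomy, so this is by construction,
not a separate fitting step. Categories are not applicable to every word
(only five DSW words carry an acute/circumflex, so AAW has sparse support);
drawing naively per word would therefore shift the realized mix toward the
universally applicable operators. Per-word category weights are calibrated
by iterative proportional fitting so that the corpus-level expected mix
equals the profile mix.

What the generator does *not* emulate: per-word difficulty heterogeneity
(the real data show strong word effects; an optional per-word rate vector
can be supplied), student-level severity heterogeneity, orthographically
plausible *invented* words, and handwriting-level phenomena (the OTHER
operator only emits the fixed lexical list). Passing round-trip and
parameter-recovery tests therefore shows the pipeline is consistent under
the taxonomy's own error model — not that it matches the full variability
of child handwriting.

## Problem sizes and verification

The test suite verifies: segmentation round-trips over random strings;
per-unit phoneme coverage over all 60 targets; script application and an
independent dynamic-programming cost oracle over all ~290 gold pairs; Fisher
against exhaustive enumeration (all tables with N ≤ 15 in the unit tests,
N ≤ 40 in the acceptance checks); Mann–Whitney against full rank-assignment
enumeration for n₁,n₂ ≤ 6; gold containment (taxonomy table complete;
≥ 90% required on the unambiguous per-word-analysis subset); a 1,000-draw
single-operator round trip; and parameter recovery pooled over five
simulated corpora (error rates within 3 binomial SEs; the GD label ranking
IPG_1 > IPG_2 > OIL > RPG > ASS). Five replicates are pooled because the
mix gap between IPG_2 and OIL is small (0.228 vs 0.201) and a single
~840-error corpus leaves the ordering within sampling noise.

## Known limitations

The G2P layer is deliberately minimal: it covers what the 60 targets and
their attested misspellings require, not general Portuguese (no full stress
assignment, no European Portuguese variants). The precedent cascade encodes
one expert labeling tradition; where that tradition is internally
inconsistent the classifier follows the majority pattern and the
disagreement is documented rather than hidden. The group Mann–Whitney p and
the absolute distinct-form counts of the original study cannot be
reproduced exactly because the raw per-student corpus is not printed; the
operations exist and are validated on synthetic and fixture data.
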