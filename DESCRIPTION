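Package: semiospell
Title: Semiological Classification of Brazilian Portuguese Spelling Errors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based semiological classification of spelling errors in
    Brazilian Portuguese dictation responses, distinguishing natural spelling
    errors (phoneme-level: RPG, OIL, ASS, USW) from arbitrary spelling errors
    (orthographic-lexicon level: IPG_1, IPG_2, AAW). Ships the 60-word
    'Dyslexic Sight Words' dictation lexicon with syllable, stress and
    orthographic-rule annotations, a grapheme-level aligner with adjacent
    transpositions, a grapheme-to-phoneme layer for Brazilian Portuguese, the
    group-comparison statistical layer (Fisher exact / chi-square selection,
    Mann-Whitney, Lilliefors normality), and a seeded synthetic dictation
    corpus generator with category-specific corruption operators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
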