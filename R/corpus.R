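# Embedded gold data: the classified error forms printed in the source
# study's taxonomy table (source "tab1") and per-word analyses (source
# "s41"), the per-word correct/incorrect counts, and the per-grade incorrect
# totals. Fixtures are constants validated by checksum at load.
#
# group: GD (dyslexia), GWD (without), both. ambiguous=1 flags records whose
# printed label conflicts with the same text's treatment of an identical
# pattern elsewhere (kept as annotations, excluded from the unambiguous
# subset). labels are '+'-separated category codes.

.GOLD_TABLE <- "word_id|form|group|labels|source|ambiguous
7|quancequio|GD|RPG|tab1|0
36|enjeiga|GD|RPG|tab1|0
33|terrepende|GD|RPG|tab1|0
7|cosegiu|GD|OIL|tab1|0
27|alcaldo|GD|OIL|tab1|0
35|ebaixo|GD|OIL|tab1|0
27|alçato|GD|ASS|tab1|0
27|ausato|GD|ASS|tab1|0
49|amahan|GD|ASS|tab1|0
35|em baixo|GWD|USW|tab1|0
23|porisso|GD|USW|tab1|0
25|agenti|GD|IPG_1|tab1|0
11|ezenpo|GD|IPG_1|tab1|1
36|emxergar|both|IPG_1|tab1|0
10|quera|GD|IPG_1|tab1|0
53|isami|GD|IPG_2|tab1|0
4|tabei|GD|IPG_2|tab1|0
32|comessou|GD|IPG_2|tab1|0
42|ningen|GD|AAW|tab1|0
50|arvore|GWD|AAW|tab1|0
33|derepente|both|USW|s41|0
33|derrepente|both|USW|s41|0
33|terrepende|GD|USW+RPG|s41|0
33|direpente|GD|USW+RPG|s41|0
33|terepeite|GD|USW+RPG|s41|0
7|quancequio|GD|RPG+IPG_1|s41|0
7|consiquil|GD|RPG+IPG_1|s41|0
7|consequil|GD|RPG+IPG_1|s41|0
7|concequio|GD|RPG+IPG_1|s41|0
7|cocegir|GD|RPG+OIL+IPG_1|s41|0
7|cosegiu|GD|OIL+IPG_1|s41|0
7|cocegiu|GD|OIL+IPG_1|s41|0
7|comseguiu|GD|IPG_1|s41|0
7|comsegiu|GD|IPG_1|s41|0
7|consegil|GD|IPG_1|s41|0
7|consegio|GD|IPG_1|s41|0
7|consegiu|GD|IPG_1|s41|0
7|conseguio|GD|IPG_1|s41|0
7|conceguio|GD|IPG_1|s41|0
7|conseguil|GD|IPG_1|s41|0
25|agente|both|USW|s41|0
25|aje te|GD|USW+OIL+IPG_2|s41|0
25|ajeite|GD|USW+RPG+IPG_2|s41|0
25|agende|GD|USW+RPG|s41|0
25|agenti|GD|USW+IPG_1|s41|0
25|ajente|GD|USW+IPG_2|s41|0
23|porisso|both|USW|s41|0
23|puriso|GD|USW+RPG+IPG_2|s41|0
23|porcio|GD|USW+ASS+IPG_2|s41|0
23|poriso|GD|USW+IPG_2|s41|0
23|poriço|GD|USW+IPG_2|s41|0
42|ningen|GD|IPG_2+IPG_1+AAW|s41|0
42|nigei|GD|IPG_2+IPG_1+OIL+AAW|s41|0
42|mingen|GD|IPG_2+IPG_1+AAW|s41|0
42|ningem|GD|IPG_1|s41|0
42|niguem|GD|OIL+AAW|s41|0
42|ningue|GD|OIL+AAW|s41|0
42|ninque|GD|OIL+RPG+AAW|s41|0
42|mimguem|GD|RPG|s41|0
42|ninquem|GD|RPG+AAW|s41|0
27|asalto|both|IPG_2|s41|0
27|asauto|both|IPG_2|s41|0
27|açalto|GD|IPG_2|s41|0
27|auçato|GD|IPG_2+ASS|s41|0
27|ausato|GD|IPG_2+ASS|s41|0
27|alçato|GD|IPG_2+ASS|s41|0
27|assauto|GD|IPG_2|s41|0
27|acauto|GD|IPG_2+RPG|s41|0
27|assatou|GD|ASS|s41|0
27|alcaldo|GD|OIL+RPG|s41|0
48|alguem|GWD|AAW|s41|0
48|algem|GD|IPG_1+AAW|s41|0
48|augen|GD|IPG_1+IPG_2+AAW|s41|0
48|amgen|GD|IPG_1+IPG_2+RPG+AAW|s41|0
48|alqen|GD|IPG_2+RPG+AAW|s41|0
48|alquém|GD|RPG|s41|0
53|ezaime|GD|OIL+IPG_1|s41|0
53|exaime|GD|OIL|s41|0
53|ezami|GD|IPG_1|s41|0
53|esami|GD|IPG_1|s41|0
53|esame|GD|IPG_1|s41|0
53|exami|GWD|IPG_1|s41|0
53|isami|GD|IPG_2+IPG_1|s41|0
35|em baixo|GWD|USW|s41|0
35|em baicho|GD|USW+IPG_1|s41|0
35|embaiso|GD|RPG|s41|0
35|embaijo|GD|RPG|s41|0
35|enbaço|GD|RPG+OIL+IPG_1|s41|0
35|ebaixo|GD|OIL|s41|0
35|embaicho|GD|IPG_1|s41|0
35|enbaichu|GD|IPG_1|s41|0
40|feis|GD|IPG_2+OIL|s41|0
40|feize|GD|OIL|s41|0
40|feiz|GD|OIL|s41|0
38|fais|GD|IPG_2+OIL|s41|0
38|fas|GD|IPG_2|s41|0
34|ensima|GD|USW+IPG_1+IPG_2|s41|0
34|emcima|both|USW|s41|0
34|incima|GD|USW+IPG_1+IPG_2|s41|0
34|enssima|GD|USW+IPG_1+IPG_2|s41|0
34|encina|GD|USW+IPG_1+RPG|s41|0
34|emicima|GD|USW+OIL|s41|0
34|emsima|GWD|USW+IPG_2|s41|0
4|tambem|GWD|AAW|s41|0
4|tabei|GD|IPG_2+OIL+AAW|s41|0
4|tanbei|GD|IPG_2+IPG_1+OIL+AAW|s41|0
4|tanbe|GD|IPG_1+OIL+AAW|s41|0
4|tanpem|GD|IPG_1+RPG+AAW|s41|0
4|tanbem|GD|IPG_1+AAW|s41|0
4|tabem|GD|OIL+AAW|s41|0
4|dampem|GD|RPG+AAW|s41|0
11|esenplo|GD|IPG_1|s41|0
11|esenplu|GD|IPG_1|s41|0
11|eseplo|GD|IPG_1+OIL|s41|0
11|esemplo|GD|IPG_1|s41|0
11|ezenplu|GD|IPG_1|s41|0
11|ezenplo|GD|IPG_1|s41|0
11|ezenpo|GD|IPG_1+OIL|s41|1
11|ezeblo|GD|IPG_1+RPG+OIL|s41|0
11|ezemplo|GD|IPG_1|s41|0
11|exenplo|GWD|IPG_1|s41|0
11|egenpo|GD|RPG+OIL|s41|0
11|exsemplo|GD|OIL|s41|0
11|enxemplo|GD|OIL|s41|0
11|exmplo|GD|OIL|s41|0
36|emxergar|both|IPG_1|s41|0
36|enchergar|both|IPG_1|s41|0
36|enchega|GD|IPG_1+OIL|s41|0
36|enjergar|GWD|RPG|s41|0
36|enjeiga|GD|RPG+OIL|s41|0
36|enserga|GD|RPG+OIL|s41|0
36|ençega|GD|RPG+OIL|s41|0
10|querra|GD|RPG|s41|0
10|quera|GD|RPG+IPG_1|s41|0
10|guera|GD|IPG_1|s41|0
10|gera|GD|IPG_1|s41|0
10|gerra|GD|IPG_1|s41|0
31|caio|GD|IPG_1|s41|0
31|caío|GD|IPG_1+AAW|s41|0
32|comesou|both|IPG_2|s41|0
32|comessou|GD|IPG_2|s41|0
32|comesol|GD|IPG_2+IPG_1|s41|0
32|comeisou|GD|IPG_2+OIL|s41|0
32|comeco|GD|RPG+OIL|s41|0
32|comecou|GD|RPG|s41|0
26|almoso|both|IPG_2|s41|0
26|almouso|GD|IPG_2+OIL|s41|0
26|aumoso|GD|IPG_2|s41|0
26|aumoço|GD|IPG_2|s41|0
26|au moço|GD|IPG_2+USW|s41|0
26|almoção|GD|OTHER|s41|0
5|fez|GD|RPG|s41|0
5|veiz|GD|OIL|s41|0
5|veis|GD|OIL+IPG_2|s41|0
5|ves|GD|IPG_2|s41|0
56|relogio|GWD|AAW|s41|0
56|relojo|GD|AAW+IPG_2+OIL|s41|0
56|relozo|GD|AAW+RPG+OIL|s41|0
22|geito|both|IPG_2|s41|0
22|geitu|GD|IPG_2+IPG_1|s41|0
22|jento|GD|RPG|s41|0
22|jeto|GD|OIL|s41|0
3|dice|GD|IPG_1|s41|0
3|dici|GD|IPG_1|s41|0
3|dise|GD|IPG_1|s41|0
3|diçe|GD|IPG_1|s41|0
50|arvore|GWD|AAW|s41|0
50|avori|GD|AAW+OIL+IPG_2|s41|0
50|arvoré|GD|AAW|s41|0
50|ávore|GD|OIL|s41|0
57|saldade|both|IPG_1|s41|1
57|saltade|GD|IPG_1+RPG|s41|1
57|çaudade|GD|IPG_1|s41|1
57|caudade|GD|RPG|s41|0
43|pege|both|IPG_1|s41|0
43|pegi|GD|IPG_1|s41|0
43|pegui|GD|IPG_1|s41|0
43|peque|GD|RPG|s41|0
28|borraja|GD|RPG|s41|0
28|boraja|GD|RPG+IPG_1|s41|0
28|borasa|GD|RPG+IPG_1|s41|0
28|boraija|GD|RPG+OIL|s41|0
28|boraxa|GD|IPG_1+IPG_2|s41|0
28|borraxa|GD|IPG_2|s41|0
28|boracha|both|IPG_1|s41|0
13|aci|GD|OIL+IPG_2|s41|0
13|assi|GD|OIL|s41|0
13|acim|GD|IPG_2|s41|0
13|asim|GD|IPG_2|s41|0
13|assin|GWD|IPG_1|s41|1
49|amanha|both|IPG_1|s41|0
49|amanham|GD|IPG_1|s41|0
49|amahan|GD|IPG_1+ASS|s41|0
52|corre|both|OIL|s41|0
52|corer|GD|IPG_1|s41|0
21|homen|both|IPG_2|s41|0
21|homin|GD|IPG_2+RPG|s41|0
21|homei|GD|IPG_2|s41|0
21|omen|GD|IPG_2|s41|0
21|omei|GD|IPG_2|s41|0
21|omem|GD|IPG_2|s41|0
21|home|GD|OIL|s41|0
14|brica|GD|OIL|s41|0
14|bincar|GD|OIL|s41|0
14|binca|GD|OIL|s41|0
14|bicar|GD|OIL|s41|0
14|brinca|GD|OIL|s41|0
14|princar|GD|RPG|s41|0
9|jende|GD|RPG+IPG_2|s41|0
9|jete|GD|OIL+IPG_2|s41|0
9|jeti|GD|OIL+IPG_2+IPG_1|s41|0
9|genti|GD|IPG_1|s41|0
9|jente|GD|IPG_2|s41|0
24|viaja|both|OIL|s41|0
24|viagar|GD|IPG_1|s41|0
51|serto|GD|IPG_2|s41|0
51|sertu|GD|IPG_2+IPG_1|s41|0
8|emcontrou|GD|IPG_1|s41|0
8|encomtrou|GD|IPG_1|s41|0
8|encomtrol|GD|IPG_1|s41|0
8|emcomtrol|GD|IPG_1|s41|0
8|encontrol|GD|IPG_1|s41|0
8|incontrol|GD|IPG_1+IPG_2|s41|0
8|incontrou|GD|IPG_2|s41|0
8|encontro|GD|OIL|s41|0
8|encontor|GD|OIL+ASS|s41|0
46|qenti|GD|IPG_1|s41|0
46|qente|GD|IPG_1|s41|0
46|quenti|GD|IPG_1|s41|0
46|queinte|GD|OIL|s41|0
46|guente|GWD|RPG|s41|0
30|cabesa|GD|IPG_2|s41|0
30|cabessa|GD|IPG_2|s41|0
30|cabeca|GD|RPG|s41|0
45|profesora|GD|IPG_2|s41|0
54|felis|GD|IPG_2|s41|0
15|futball|GWD|OTHER|s41|0
15|fotebol|both|IPG_2|s41|0
15|futibol|GD|IPG_2|s41|0
15|futibou|GD|IPG_2|s41|0
15|futebou|GD|IPG_2|s41|0
15|fultebol|both|OIL|s41|0
15|futeboll|GD|OIL|s41|0
47|tenhor|GWD|OIL|s41|0
47|teinho|GD|OIL|s41|0
47|teo|GD|OIL|s41|0
47|temum|GD|OTHER|s41|0
47|teiu|GD|RPG+IPG_1|s41|0
58|tenpo|both|IPG_1|s41|0
58|tenpu|GD|IPG_1|s41|0
58|tepo|GD|OIL|s41|0
59|dezora|GD|RPG+OIL+IPG_2|s41|0
59|tezoura|GD|IPG_2|s41|0
39|faze|GD|OIL|s41|0
39|vazer|GD|RPG|s41|0
39|faser|GD|IPG_2|s41|0
12|aguda|GD|IPG_1|s41|0
12|axuda|GD|RPG|s41|0
12|ajudar|GD|OIL|s41|0
1|muinto|both|OIL|s41|0
1|munito|GD|OIL|s41|0
1|muitu|GD|IPG_1|s41|0
20|emtão|GWD|IPG_1|s41|0
20|entam|GD|IPG_1|s41|0
20|intau|GD|IPG_1+IPG_2|s41|0
20|eitão|GD|RPG|s41|0
2|guando|GD|RPG|s41|0
2|gando|GD|RPG+OIL|s41|0
2|cando|GD|RPG|s41|0
2|cuado|GD|OIL+IPG_2|s41|0
2|quamdo|GD|IPG_1|s41|0
6|cachoro|GD|IPG_1|s41|0
6|caxoro|GD|IPG_1+IPG_2|s41|0
55|prezenti|GD|IPG_1+IPG_2|s41|0
55|prezente|GD|IPG_2|s41|0
55|prezete|GD|IPG_2+OIL|s41|0
29|bruça|GD|RPG|s41|0
29|bruja|GD|RPG|s41|0
29|bruija|GD|RPG+OIL|s41|0
29|brucha|GD|IPG_2|s41|0
17|animao|GD|IPG_2|s41|0
17|animau|GD|IPG_2|s41|0
41|jirafa|GD|IPG_2|s41|0
41|girrafa|GD|IPG_1|s41|0
18|caro|GD|IPG_1|s41|0
60|galilha|GD|RPG|s41|0
44|poorgue|GD|RPG+OIL|s41|0
44|poque|GD|OIL|s41|0
44|proque|GD|ASS|s41|0
16|minino|GD|IPG_2|s41|0"

# Per-word correct/incorrect counts, 30 students per group. The GWD cell for
# 'disse' is printed as "28 (933%)" in the source; stored as 28/2 (the
# percentage is a typo for 93.3%).
.TABLE3 <- "word_id|gd_correct|gd_incorrect|gwd_correct|gwd_incorrect
1|23|7|29|1
2|24|6|30|0
3|13|17|28|2
4|8|22|25|5
5|11|19|30|0
6|24|6|30|0
7|2|28|19|11
8|19|11|30|0
9|18|12|30|0
10|9|21|29|1
11|9|21|28|2
12|22|8|30|0
13|15|15|29|1
14|17|13|30|0
15|21|9|27|3
16|29|1|30|0
17|26|4|30|0
18|27|3|30|0
19|30|0|30|0
20|24|6|28|2
21|17|13|29|1
22|12|18|29|1
23|3|27|24|6
24|18|12|29|1
25|2|28|20|10
26|10|20|28|2
27|4|26|24|6
28|14|16|29|1
29|25|5|30|0
30|20|10|30|0
31|9|21|30|0
32|10|20|29|1
33|1|29|21|9
34|8|22|24|6
35|7|23|24|6
36|9|21|24|6
37|30|0|30|0
38|8|22|29|1
39|22|8|30|0
40|7|23|29|1
41|26|4|30|0
42|3|27|20|10
43|14|16|29|1
44|27|3|30|0
45|20|10|30|0
46|19|11|29|1
47|22|8|29|1
48|4|26|25|5
49|15|15|27|3
50|13|17|28|2
51|18|12|30|0
52|16|14|27|3
53|6|24|26|4
54|21|9|30|0
55|24|6|30|0
56|11|19|24|6
57|14|16|27|3
58|22|8|27|3
59|22|8|30|0
60|27|3|30|0"

# Per-grade totals of incorrectly written words (dictation of 60 words).
.GRADE_TOTALS <- "grade|group|n_students|total_incorrect
3|GD|10|387
3|GWD|10|62
4|GD|8|236
4|GWD|8|37
5|GD|4|93
5|GWD|4|19
6|GD|8|133
6|GWD|8|10"

.FIXTURE_MD5 <- c(gold = "bf901271e57618b07d7c87d6bfd7ef5c",
                  table3 = "3b171df2dff5c620eaf5e916cc81d6e2",
                  grades = "5450617e01a2aba80048ad1ae5751f75")

fixture_checksum <- function(text) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(charToRaw(enc2utf8(text)), tf)
  unname(tools::md5sum(tf))
}

check_fixture <- function(text, which) {
  expected <- .FIXTURE_MD5[[which]]
  if (!grepl("^@", expected) && !identical(fixture_checksum(text), expected)) {
    stop("integrity_error: embedded fixture '", which,
         "' failed its checksum; the installation is corrupted")
  }
  invisible(TRUE)
}

#' Gold-annotated misspelled forms from the source study
#'
#' Error forms transcribed from the taxonomy table (`source == "tab1"`) and
#' from the per-word analyses (`source == "s41"`), each with its stated
#' category set. `ambiguous` flags records whose printed label conflicts with
#' the treatment of the identical pattern elsewhere in the same text; the
#' unambiguous subset is the containment benchmark.
#'
#' @return Data frame: `word_id`, `form`, `group`, `labels` (list column of
#'   category codes), `source`, `ambiguous`.
#' @export
gold_fixture <- function() {
  check_fixture(.GOLD_TABLE, "gold")
  df <- utils::read.delim(text = .GOLD_TABLE, sep = "|", quote = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  df$labels <- strsplit(df$labels, "+", fixed = TRUE)
  df$ambiguous <- df$ambiguous == 1
  lex <- dsw_lexicon()
  stopifnot(all(df$word_id %in% lex$word_id),
            all(lengths(df$labels) > 0),
            all(unlist(df$labels) %in% .CATEGORIES),
            all(df$group %in% c("GD", "GWD", "both")))
  tgt <- lex$form[match(df$word_id, lex$word_id)]
  norm <- vapply(df$form, normalize_form, character(1), USE.NAMES = FALSE)
  stopifnot(all(norm != tgt))
  df
}

#' Per-word correct/incorrect counts by group
#'
#' The 60 x 2 correct/incorrect tabulation (30 students per group) used by
#' the per-word association tests.
#'
#' @return Data frame: `word_id`, `form`, `gd_correct`, `gd_incorrect`,
#'   `gwd_correct`, `gwd_incorrect`.
#' @examples
#' counts <- table3_counts()
#' counts[counts$form == "quando", ]
#' @export
table3_counts <- function() {
  check_fixture(.TABLE3, "table3")
  df <- utils::read.delim(text = .TABLE3, sep = "|", quote = "",
                          stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 60L,
            all(df$gd_correct + df$gd_incorrect == 30L),
            all(df$gwd_correct + df$gwd_incorrect == 30L))
  lex <- dsw_lexicon()
  df <- cbind(word_id = df$word_id, form = lex$form[df$word_id],
              df[, -1], stringsAsFactors = FALSE)
  df
}

#' Per-grade totals of incorrectly written words
#'
#' @return Data frame: `grade`, `group`, `n_students`, `total_incorrect`.
#' @export
grade_totals <- function() {
  check_fixture(.GRADE_TOTALS, "grades")
  df <- utils::read.delim(text = .GRADE_TOTALS, sep = "|", quote = "",
                          stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 8L, all(df$group %in% c("GD", "GWD")))
  df
}

#' Read a dictation response table
#'
#' Comma-delimited UTF-8 with header columns `student_id`, `group`, `grade`,
#' `word_id`, `written_form`. Malformed rows are collected into an error
#' report attached as attribute `"errors"`, not silently dropped.
#'
#' @param path File path.
#' @return Data frame of valid responses; `attr(, "errors")` holds a data
#'   frame of rejected rows with a `reason` column.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  required <- c("student_id", "group", "grade", "word_id", "written_form")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, required]
  df$grade <- suppressWarnings(as.integer(df$grade))
  df$word_id <- suppressWarnings(as.integer(df$word_id))
  reason <- rep(NA_character_, nrow(df))
  reason[!(df$group %in% c("GD", "GWD"))] <- "bad group"
  bad_grade <- is.na(df$grade) | df$grade < 3L | df$grade > 6L
  reason[is.na(reason) & bad_grade] <- "bad grade"
  bad_word <- is.na(df$word_id) | df$word_id < 1L | df$word_id > 60L
  reason[is.na(reason) & bad_word] <- "bad word_id"
  ok <- is.na(reason)
  errors <- df[!ok, , drop = FALSE]
  if (nrow(errors)) errors$reason <- reason[!ok]
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Write a dictation response table
#'
#' Inverse of [read_responses()]; round-trip stable.
#' @param responses Response data frame.
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses[, c("student_id", "group", "grade", "word_id",
                                 "written_form")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a classification output table
#'
#' One row per (response, label) with locus, rationale and edit-script
#' notation; summary rows (category `"-"`) carry the verdict for responses
#' without labels.
#' @param classified Data frame from [classify_responses()].
#' @param path File path.
#' @export
write_classifications <- function(classified, path) {
  utils::write.csv(classified, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export embedded fixtures for inspection
#'
#' Writes the lexicon, the gold fixture, the per-word counts and the grade
#' totals to delimited files in `dir`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    if (!is.null(df$labels) && is.list(df$labels)) {
      df$labels <- vapply(df$labels, paste, character(1), collapse = "+")
    }
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  lex <- dsw_lexicon()
  attr(lex, "syllable_spans") <- NULL
  wr(as.data.frame(lex), "dsw_lexicon.csv")
  wr(gold_fixture(), "gold_fixture.csv")
  wr(table3_counts(), "table3_counts.csv")
  wr(grade_totals(), "grade_totals.csv")
  invisible(paths)
}
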