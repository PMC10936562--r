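# Shared fixtures and independent oracles used across the suite.

LEX <- dsw_lexicon()
GOLD <- gold_fixture()
T3 <- table3_counts()

# Brute-force edit-distance oracle: plain dynamic programming over grapheme
# units WITHOUT transpositions, using the same substitution cost function as
# the implementation but an independent recurrence (no backtrace, no OSA
# extension). Used to bound/verify align_graphemes costs.
oracle_dp_cost <- function(target, response, word_meta = NULL) {
  tgs <- segment_graphemes(normalize_form(target))
  rgs <- segment_graphemes(normalize_form(response))
  tu <- tgs$units; ru <- rgs$units
  x_sound <- if (!is.null(word_meta) && isTRUE(word_meta$x_reads_z)) "z" else NULL
  n <- length(tu); m <- length(ru)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      sc <- semiospell:::sub_cost(tu, i, ru, j, x_sound)
      cur[j + 1L] <- min(prev[j] + sc, prev[j + 1L] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Exhaustive Fisher oracle: for the observed 2x2 table, enumerate every
# table with the same margins and sum the hypergeometric probabilities not
# exceeding the observed table's probability.
oracle_fisher_p <- function(t) {
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); N <- sum(t)
  a_min <- max(0L, r1 + c1 - N); a_max <- min(r1, c1)
  avals <- a_min:a_max
  probs <- dhyper(avals, c1, N - c1, r1)
  p_obs <- dhyper(t[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive Mann-Whitney oracle for small untied samples: enumerate every
# assignment of ranks to the first sample and compute the two-sided p of the
# rank-sum statistic.
oracle_mw_p <- function(xs, ys) {
  n1 <- length(xs); n <- n1 + length(ys)
  stopifnot(!anyDuplicated(c(xs, ys)))
  r_obs <- sum(rank(c(xs, ys))[seq_len(n1)])
  combs <- utils::combn(n, n1)
  sums <- colSums(matrix(seq_len(n)[combs], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(r_obs - mu) - 1e-9)
}

# Predicted category set for a gold record.
predicted_for <- function(word_id, form) {
  cl <- classify_spelling(word_id, form, lexicon = LEX)
  if (cl$verdict == "other") "OTHER" else predicted_categories(cl)
}

# Random lowercase word over the plain Portuguese alphabet (for segmentation
# round-trip properties).
random_form <- function(len) {
  paste(sample(c(letters[1:26], "ç", "á", "é", "ã", "õ"), len, replace = TRUE),
        collapse = "")
}
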