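# Independent oracles and random-case generators shared across the suite.
# The matcher oracle enumerates every (start, expansion) combination
# explicitly, trying repeat counts in ascending order element by element
# (the same lexicographic order the leftmost-shortest convention defines),
# and is deliberately independent of the regex-based scan path.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_element_ok <- function(e, ch) {
  switch(e$mode,
    wildcard = TRUE,
    `fixed-set` = ch %in% e$allowed,
    `negated-set` = !(ch %in% e$allowed))
}

# first admissible end position (0-based exclusive) for a match starting at
# `pos` (0-based), or -1; repeat counts tried in ascending order
oracle_match_from <- function(chars, elements, pos, ei) {
  if (ei > length(elements)) return(pos)
  e <- elements[[ei]]
  for (k in e$min_repeat:e$max_repeat) {
    if (pos + k > length(chars)) next
    seg <- chars[(pos + 1):(pos + k)]
    if (all(vapply(seg, function(ch) oracle_element_ok(e, ch), TRUE))) {
      r <- oracle_match_from(chars, elements, pos + k, ei + 1L)
      if (r >= 0) return(r)
    }
  }
  -1L
}

oracle_matches <- function(pattern, s) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  s <- toupper(s)
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  starts <- if (pattern$anchor_start) 0L else 0:max(L - 1L, 0L)
  out <- list()
  for (a in starts) {
    if (L == 0L) break
    b <- oracle_match_from(chars, pattern$elements, a, 1L)
    if (b >= 0 && (!pattern$anchor_end || b == L)) {
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b,
        matched = substring(s, a + 1L, b),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      matched = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# random PROSITE pattern over a restricted alphabet (so random sequences
# actually produce matches); returns the pattern text
random_pattern_text <- function(n_elements, alphabet = c("A", "C", "D", "G"),
                                fixed_span = FALSE) {
  reps <- if (fixed_span) c("", "(2)", "(3)") else
    c("", "(2)", "(1,2)", "(2,4)")
  rep_prob <- if (fixed_span) c(0.7, 0.2, 0.1) else c(0.6, 0.1, 0.2, 0.1)
  elems <- vapply(seq_len(n_elements), function(i) {
    mode <- sample(c("fixed", "class", "negated", "wild"), 1L,
                   prob = c(0.35, 0.25, 0.15, 0.25))
    body <- switch(mode,
      fixed = sample(alphabet, 1L),
      class = paste0("[", paste(sort(sample(alphabet,
                                            sample(2:3, 1L))), collapse = ""), "]"),
      negated = paste0("{", paste(sort(sample(alphabet,
                                              sample(1:2, 1L))), collapse = ""), "}"),
      wild = "x")
    rep <- sample(reps, 1L, prob = rep_prob)
    paste0(body, rep)
  }, "")
  paste(elems, collapse = "-")
}

random_sequence <- function(max_len, alphabet = c("A", "C", "D", "G")) {
  L <- sample.int(max_len, 1L)
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# random additive tree fixture: a rooted random topology with strictly
# positive branch lengths, plus its exact path-length distance matrix
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, D = stats::cophenetic(tr))
}
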