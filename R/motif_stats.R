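#' Background residue-composition models
#'
#' An order-0 (Bernoulli / i.i.d.) background model is a probability vector
#' over the 20 standard amino acids. [estimate_background()] fits the
#' maximum-likelihood letter proportions of a sequence collection;
#' non-standard letters (B, J, O, U, X, Z) are excluded from both numerator
#' and denominator. [uniform_background()] returns the flat 1/20 model.
#'
#' @param sequences named character vector of sequences.
#' @return A named numeric vector of class `background_model` over the
#'   20-letter alphabet, summing to 1.
#' @examples
#' estimate_background(c(a = "AAC", b = "C"))
#' @export
estimate_background <- function(sequences) {
  sequences <- check_sequences(sequences)
  letters_ <- strsplit(paste(sequences, collapse = ""), "")[[1]]
  counts <- table(factor(letters_, levels = AA_STANDARD))
  total <- sum(counts)
  if (total == 0L)
    stop("collection contains no standard residues", call. = FALSE)
  background_model(as.numeric(counts) / total)
}

#' @rdname estimate_background
#' @export
uniform_background <- function() {
  background_model(rep(1 / 20, 20L))
}

#' @rdname estimate_background
#' @param frequencies numeric vector of 20 probabilities, optionally named
#'   by residue letter (unnamed vectors are taken in alphabetical order).
#' @export
background_model <- function(frequencies) {
  if (is.null(names(frequencies))) {
    if (length(frequencies) != 20L)
      stop("unnamed frequency vectors must have length 20", call. = FALSE)
    names(frequencies) <- AA_STANDARD
  }
  bad <- setdiff(names(frequencies), AA_STANDARD)
  if (length(bad))
    stop("background support outside the 20-letter alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  f <- stats::setNames(numeric(20L), AA_STANDARD)
  f[names(frequencies)] <- as.numeric(frequencies)
  if (any(f < 0))
    stop("background frequencies must be non-negative", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-9)
    stop("background frequencies must sum to 1 (got ", sum(f), ")",
         call. = FALSE)
  structure(f, class = "background_model")
}

## Per-element single-position match probability under a background.
element_probability <- function(e, background) {
  switch(e$mode,
    wildcard      = 1,
    `fixed-set`   = sum(background[e$allowed]),
    `negated-set` = 1 - sum(background[e$allowed]))
}

#' Per-site match probability of a pattern under a background
#'
#' For a fixed-span pattern the probability that a window of the pattern's
#' span, drawn i.i.d. from the background, matches is the product of the
#' per-position probabilities: the summed frequency of a fixed residue set,
#' one minus the summed frequency of a negated set, and 1 for a wildcard.
#' Variable-span patterns are expanded over all fixed-span realizations of
#' their repeat ranges; the per-span probabilities are accumulated by
#' polynomial convolution, so the cost is linear in the span range rather
#' than exponential in the number of variable elements.
#'
#' @inheritParams find_matches
#' @param background a `background_model`.
#' @return For a fixed-span pattern, a single probability with attribute
#'   `span`. For a variable-span pattern, a data frame with columns `span`
#'   and `p` (one row per realized span; `p` sums the probabilities of all
#'   expansions of that span).
#' @examples
#' per_site_probability("A", uniform_background())  # 0.05
#' @export
per_site_probability <- function(pattern, background) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"),
            inherits(background, "background_model"))
  tab <- span_probabilities(pattern, background)
  if (nrow(tab) == 1L)
    structure(tab$p, span = tab$span)
  else
    tab
}

## data.frame(span, p): coefficient of z^span in prod_e sum_k (q_e z)^k
span_probabilities <- function(pattern, background) {
  poly <- 1 # coefficients over spans, starting at offset 0
  offset <- 0L
  for (e in pattern$elements) {
    q <- element_probability(e, background)
    reps <- e$min_repeat:e$max_repeat
    epoly <- q^reps
    poly <- convolve_full(poly, epoly)
    offset <- offset + e$min_repeat
  }
  spans <- offset + seq_along(poly) - 1L
  data.frame(span = spans, p = as.numeric(poly))
}

convolve_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Expected number of random pattern matches in a collection
#'
#' Under the i.i.d. background, the expected number of matching windows in a
#' sequence of length L is `sum_s max(0, L - s + 1) * p_s` over the
#' pattern's realized spans s; the expectation is additive over sequences.
#' Overlap between windows (and mutual exclusivity of different expansions
#' at one window) is ignored, which makes the variable-span value a slight
#' upper bound; [monte_carlo_expectation()] quantifies the approximation.
#'
#' @inheritParams per_site_probability
#' @param lengths integer vector of sequence lengths.
#' @return Expected match count (a single number).
#' @examples
#' expected_matches("A", uniform_background(), 20)  # 1.0
#' @export
expected_matches <- function(pattern, background, lengths) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(all(lengths >= 0))
  tab <- span_probabilities(pattern, background)
  sum(vapply(lengths, function(L)
    sum(pmax(0, L - tab$span + 1) * tab$p), 0))
}

#' Monte-Carlo estimate of the expected match count
#'
#' Draws `n_reps` i.i.d. sequence collections from the background, counts
#' matches with [find_matches()] under the all-starts policy, and returns
#' the sample mean and standard error. Serves as the simulation oracle for
#' [expected_matches()].
#'
#' @inheritParams expected_matches
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return A list with `mean`, `se` (NA when `n_reps == 1`) and `n_reps`.
#' @export
monte_carlo_expectation <- function(pattern, background, lengths,
                                    n_reps = 1000, seed = NULL) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(n_reps >= 1)
  counts <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      seqs <- draw_background(length(lengths), lengths, background)
      nrow(scan_collection(pattern, seqs))
    }, 0)
  })
  list(mean = mean(counts),
       se = if (n_reps > 1) stats::sd(counts) / sqrt(n_reps) else NA_real_,
       n_reps = n_reps)
}

## internal unseeded draw used by generators and the Monte-Carlo oracle
draw_background <- function(n, lengths, background) {
  lengths <- rep_len(as.integer(lengths), n)
  seqs <- vapply(lengths, function(L)
    paste(sample(AA_STANDARD, L, replace = TRUE, prob = as.numeric(background)),
          collapse = ""), "")
  names(seqs) <- sprintf("seq%d", seq_len(n))
  seqs
}

#' Observed-versus-expected enrichment of a pattern in a collection
#'
#' Counts observed matches with [scan_collection()], computes the expected
#' random count with [expected_matches()] on the same collection's lengths,
#' and reports the enrichment ratio O/E. When no background is supplied the
#' residue composition of the scanned collection itself is used.
#'
#' @inheritParams scan_collection
#' @param background a `background_model`, or NULL to estimate it from
#'   `sequences`.
#' @return An object of class `expectation_report`: a list with
#'   `pattern_name`, `per_site` (see [per_site_probability()]), `observed`,
#'   `expected`, `ratio` (`Inf` when `expected == 0` with observed hits,
#'   `NA` when both are zero), `n_sequences` and `total_residues`.
#' @examples
#' seqs <- c(a = "PGPDGVPNTEDD", b = "DIDIVLPGPDGILGTADDIGN")
#' enrichment_report("G-x-D-G-x(5)-D-D", seqs)
#' @export
enrichment_report <- function(pattern, sequences, background = NULL,
                              policy = c("all-starts", "non-overlapping-leftmost")) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  policy <- match.arg(policy)
  sequences <- check_sequences(sequences)
  if (is.null(background)) background <- estimate_background(sequences)
  O <- nrow(scan_collection(pattern, sequences, policy = policy))
  E <- expected_matches(pattern, background, nchar(sequences))
  ratio <- if (E > 0) O / E else if (O > 0) Inf else NA_real_
  structure(list(
    pattern_name = pattern$name,
    per_site = per_site_probability(pattern, background),
    observed = O, expected = E, ratio = ratio,
    n_sequences = length(sequences),
    total_residues = sum(nchar(sequences))),
    class = "expectation_report")
}

#' @export
print.expectation_report <- function(x, ...) {
  cat("Motif enrichment report:", x$pattern_name, "\n")
  cat(sprintf("  collection: %d sequences, %d residues\n",
              x$n_sequences, x$total_residues))
  cat(sprintf("  observed %d, expected %.4g, ratio %s\n",
              x$observed, x$expected,
              if (is.na(x$ratio)) "undefined" else
                if (is.infinite(x$ratio)) "infinite" else
                  sprintf("%.3g", x$ratio)))
  invisible(x)
}

#' Tabulate enrichment for a set of motifs
#'
#' Convenience wrapper producing one row per motif, mirroring the columns of
#' a motif/observed/expected/ratio report table.
#'
#' @param patterns a named character vector of pattern strings, or a list of
#'   `prosite_pattern` objects.
#' @inheritParams enrichment_report
#' @return A data frame with columns `motif`, `observed`, `expected`, `ratio`.
#' @export
enrichment_table <- function(patterns, sequences, background = NULL) {
  if (is.character(patterns)) {
    nm <- names(patterns) %||% patterns
    patterns <- Map(parse_prosite, patterns, nm)
  }
  rows <- lapply(patterns, function(p) {
    r <- enrichment_report(p, sequences, background = background)
    data.frame(motif = r$pattern_name, observed = r$observed,
               expected = r$expected, ratio = r$ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a background composition table
#'
#' Plain TSV with two columns, residue letter and frequency; `#` comment
#' lines are ignored.
#'
#' @param path file path.
#' @return [read_background()] returns a `background_model`.
#' @export
read_background <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("residue", "frequency"),
                           stringsAsFactors = FALSE)
  background_model(stats::setNames(tab$frequency, toupper(tab$residue)))
}

#' @rdname read_background
#' @param background a `background_model`.
#' @export
write_background <- function(background, path) {
  stopifnot(inherits(background, "background_model"))
  utils::write.table(
    data.frame(residue = names(background), frequency = as.numeric(background)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
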