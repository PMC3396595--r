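#' Parse a PROSITE-syntax motif pattern
#'
#' Parses a linear protein motif written in PROSITE pattern syntax into an
#' ordered list of elements, each a fixed residue set, a negated set or a
#' wildcard, with optional repeat counts. The grammar accepts single residue
#' letters (`D`), residue classes (`[GN]`), negations (`{G}`, any residue
#' except those listed), the wildcard `x`, repeat suffixes `(n)` and `(n,m)`
#' on any element, the N/C-terminal anchors `<` and `>`, and the slash
#' shorthand `D/E` as a synonym of the class `[DE]`. Elements are separated
#' by `-`; whitespace and a trailing `.` are ignored.
#'
#' @param text pattern string, e.g. `"G-x-D-G-x(2)-[GN]-[TN]-x-D-D"`.
#' @param name optional label carried into match tables (defaults to the
#'   canonical pattern string).
#' @return An object of class `prosite_pattern`: a list with `name`,
#'   `elements` (each with `mode`, `allowed`, `min_repeat`, `max_repeat`),
#'   `min_span`, `max_span` and the two anchor flags.
#' @examples
#' p <- parse_prosite("G-x-D-G-x(5)-D-D")
#' p$min_span  # 11
#' format(parse_prosite("G-x-D-G-x-x-G/N-T/N-x-D-D"))
#' @seealso [find_matches()], [scan_collection()]
#' @export
parse_prosite <- function(text, name = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("pattern text must be a non-empty string", call. = FALSE)
  s <- gsub("[[:space:]]+", "", text)
  s <- sub("\\.$", "", s)
  anchor_start <- startsWith(s, "<")
  if (anchor_start) s <- substring(s, 2L)
  anchor_end <- endsWith(s, ">")
  if (anchor_end) s <- substring(s, 1L, nchar(s) - 1L)
  if (!nzchar(s)) stop("pattern has no elements", call. = FALSE)

  ## split on "-" separators that are outside brackets (classes never
  ## contain "-", so a plain split is safe)
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(toks)))
    stop("empty pattern element (stray '-') in \"", text, "\"", call. = FALSE)

  elements <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    elements[[i]] <- parse_element(toks[i], i)
  }
  min_span <- sum(vapply(elements, `[[`, 1L, "min_repeat"))
  max_span <- sum(vapply(elements, `[[`, 1L, "max_repeat"))
  pat <- structure(
    list(name = NULL, elements = elements,
         min_span = min_span, max_span = max_span,
         anchor_start = anchor_start, anchor_end = anchor_end),
    class = "prosite_pattern")
  pat$name <- name %||% format(pat)
  pat
}

parse_element <- function(tok, pos) {
  m <- regmatches(tok, regexec(
    "^(x|[A-Za-z](?:/[A-Za-z])*|\\[[^][}{]*\\]|\\{[^][}{]*\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
    tok))[[1]]
  if (length(m) == 0L)
    stop("malformed pattern element \"", tok, "\" at position ", pos,
         call. = FALSE)
  body <- m[2]
  min_rep <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  max_rep <- if (nzchar(m[4])) as.integer(m[4]) else min_rep
  if (min_rep < 1L)
    stop("repeat count must be >= 1 in element \"", tok, "\" at position ",
         pos, call. = FALSE)
  if (max_rep < min_rep)
    stop("max repeat < min repeat in element \"", tok, "\" at position ",
         pos, call. = FALSE)

  if (body == "x") {
    mode <- "wildcard"; allowed <- character(0)
  } else if (startsWith(body, "[")) {
    mode <- "fixed-set"
    allowed <- element_letters(substr(body, 2L, nchar(body) - 1L), tok, pos)
  } else if (startsWith(body, "{")) {
    mode <- "negated-set"
    allowed <- element_letters(substr(body, 2L, nchar(body) - 1L), tok, pos)
  } else {
    mode <- "fixed-set"
    allowed <- element_letters(gsub("/", "", body), tok, pos)
  }
  if (mode != "wildcard" && length(allowed) == 0L)
    stop("empty residue class in element \"", tok, "\" at position ", pos,
         call. = FALSE)
  list(mode = mode, allowed = allowed,
       min_repeat = min_rep, max_repeat = max_rep)
}

element_letters <- function(chars, tok, pos) {
  letters_ <- unique(strsplit(toupper(chars), "")[[1]])
  bad <- setdiff(letters_, AA_STANDARD)
  if (length(bad))
    stop("illegal residue letter(s) ", paste(bad, collapse = ", "),
         " in element \"", tok, "\" at position ", pos, call. = FALSE)
  letters_  # written order preserved, e.g. [TN] stays [TN]
}

#' @export
format.prosite_pattern <- function(x, ...) {
  fmt1 <- function(e) {
    body <- switch(e$mode,
      wildcard     = "x",
      `fixed-set`  = if (length(e$allowed) == 1L) e$allowed else
                       paste0("[", paste(e$allowed, collapse = ""), "]"),
      `negated-set` = paste0("{", paste(e$allowed, collapse = ""), "}"))
    rep <- if (e$min_repeat == 1L && e$max_repeat == 1L) "" else
           if (e$min_repeat == e$max_repeat) sprintf("(%d)", e$min_repeat) else
           sprintf("(%d,%d)", e$min_repeat, e$max_repeat)
    paste0(body, rep)
  }
  core <- paste(vapply(x$elements, fmt1, ""), collapse = "-")
  paste0(if (x$anchor_start) "<" else "", core, if (x$anchor_end) ">" else "")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("PROSITE pattern", shQuote(x$name), "\n")
  cat(" ", format(x), "\n")
  cat("  elements:", length(x$elements),
      " span:", if (x$min_span == x$max_span) x$min_span else
        paste0(x$min_span, "-", x$max_span), "\n")
  invisible(x)
}

## Translate one element into a PCRE fragment with a lazy quantifier, so that
## the scan below reports the leftmost-shortest expansion at each start.
element_regex <- function(e) {
  body <- switch(e$mode,
    wildcard      = "[A-Z]",
    `fixed-set`   = if (length(e$allowed) == 1L) e$allowed else
                      paste0("[", paste(e$allowed, collapse = ""), "]"),
    `negated-set` = paste0("[^", paste(e$allowed, collapse = ""), "]"))
  quant <- if (e$min_repeat == 1L && e$max_repeat == 1L) "" else
           if (e$min_repeat == e$max_repeat)
             sprintf("{%d}", e$min_repeat) else
             sprintf("{%d,%d}?", e$min_repeat, e$max_repeat)
  paste0(body, quant)
}

pattern_regex <- function(pattern) {
  paste0(vapply(pattern$elements, element_regex, ""), collapse = "")
}

#' Find all occurrences of a pattern in one protein sequence
#'
#' Scans a single sequence for a parsed PROSITE pattern. Under the default
#' `all-starts` policy every start position admitting a match is reported
#' once, at its leftmost-shortest expansion of variable wildcards; under
#' `non-overlapping-leftmost` a greedy left-to-right scan keeps only hits
#' that do not overlap an earlier kept hit. Coordinates are 0-based,
#' half-open. Sequences are uppercased on ingest; non-standard residue
#' letters (B, J, O, U, X, Z) are matched by wildcards and negated sets but
#' never by fixed residue sets.
#'
#' @param pattern a `prosite_pattern` (see [parse_prosite()]) or a pattern
#'   string, parsed on the fly.
#' @param seq a single sequence string; its id is taken from `names(seq)`
#'   or the `id` argument (default `"seq1"`).
#' @param policy overlap policy, `"all-starts"` (default) or
#'   `"non-overlapping-leftmost"`.
#' @param id sequence id overriding `names(seq)`.
#' @return A data frame with columns `sequence_id`, `pattern_name`, `start`,
#'   `end` (0-based half-open) and `matched`, sorted by `start`. Unmatchable
#'   patterns yield zero rows.
#' @examples
#' percal <- parse_prosite("G-x-D-G-x(2)-[GN]-[TN]-x-D-D", name = "PERCAL")
#' find_matches(percal, "PGPDGVPNTEDD")
#' @export
find_matches <- function(pattern, seq,
                         policy = c("all-starts", "non-overlapping-leftmost"),
                         id = NULL) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  policy <- match.arg(policy)
  if (length(seq) != 1L)
    stop("find_matches scans one sequence; use scan_collection for sets",
         call. = FALSE)
  sid <- id %||% names(seq) %||% "seq1"
  s <- check_sequences(stats::setNames(seq, sid))[[1]]

  rx <- paste0(if (pattern$anchor_start) "^" else "",
               "(?=(", pattern_regex(pattern),
               if (pattern$anchor_end) "$" else "", "))")
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_hits())
  starts <- as.integer(attr(m, "capture.start")[, 1L]) - 1L
  lens <- as.integer(attr(m, "capture.length")[, 1L])
  hits <- data.frame(
    sequence_id = sid,
    pattern_name = pattern$name,
    start = starts,
    end = starts + lens,
    matched = substring(s, starts + 1L, starts + lens),
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$start), , drop = FALSE]
  if (policy == "non-overlapping-leftmost" && nrow(hits) > 1L) {
    keep <- logical(nrow(hits))
    last_end <- -1L
    for (k in seq_len(nrow(hits))) {
      if (hits$start[k] >= last_end) {
        keep[k] <- TRUE
        last_end <- hits$end[k]
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(sequence_id = character(0), pattern_name = character(0),
             start = integer(0), end = integer(0), matched = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence collection for a pattern
#'
#' Applies [find_matches()] to every sequence in a collection and
#' concatenates the per-sequence hit tables.
#'
#' @inheritParams find_matches
#' @param sequences named character vector of sequences (names are unique ids).
#' @return A hit data frame as in [find_matches()], with an attribute
#'   `total` equal to the number of rows.
#' @examples
#' seqs <- c(pep1 = "PGPDGVPNTEDD", pep2 = "DIDIVLPGPDGILGTADDIGN")
#' scan_collection("G-x-D-G-x(5)-D-D", seqs)
#' @export
scan_collection <- function(pattern, sequences,
                            policy = c("all-starts", "non-overlapping-leftmost")) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  policy <- match.arg(policy)
  if (length(sequences) == 0L) {
    out <- empty_hits()
    attr(out, "total") <- 0L
    return(out)
  }
  sequences <- check_sequences(sequences)
  res <- lapply(names(sequences), function(sid)
    find_matches(pattern, sequences[[sid]], policy = policy, id = sid))
  hits <- do.call(rbind, c(list(empty_hits()), res))
  rownames(hits) <- NULL
  attr(hits, "total") <- nrow(hits)
  hits
}
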