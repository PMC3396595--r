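#' @keywords internal
"_PACKAGE"

## 20-letter standard amino-acid alphabet, alphabetical order.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Ambiguity / non-standard letters seen in real databases. Matched by
## wildcards and negated sets, never by fixed residue sets.
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z")

GAP_CHARS <- c("-", ".")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a temporary RNG state so that seeded generators do not
## disturb the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Validate a named character vector of protein sequences (the package-wide
## in-memory representation: names are ids, values are residue strings).
check_sequences <- function(sequences, allow_gaps = FALSE) {
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("sequences must be a non-empty named character vector", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must carry a non-empty id (vector names)", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "), call. = FALSE)
  sequences <- toupper(sequences)
  pat <- if (allow_gaps) "^[A-Z.-]*$" else "^[A-Z]*$"
  bad <- ids[!grepl(pat, sequences)]
  if (length(bad))
    stop("non-alphabetic residues in sequence(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  sequences
}
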