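#' Classify motif hits as intra- or extra-domain
#'
#' A hit is intra-domain iff its interval `[start, end)` is fully contained
#' in one of the annotated domain intervals of its protein (hits straddling
#' a domain boundary count as extra-domain). Proteins without annotated
#' domains contribute only extra-domain hits.
#'
#' @param hits a hit data frame from [find_matches()] / [scan_collection()].
#' @param domains a domain table: data frame with columns `protein_id`,
#'   `domain_label`, `start`, `end` (0-based half-open; non-overlapping per
#'   protein, labels unique per protein). See [read_domain_table()].
#' @param sequences optional named character vector; when supplied, hits
#'   extending beyond their sequence raise an error.
#' @return A list of class `hit_classification` with elements `intra` and
#'   `extra` (hit data frames; `intra` gains a `domain_label` column),
#'   `per_domain` and `per_protein` count tables, `n_domains_with_hit`,
#'   `n_proteins_with_hit` and `total`.
#' @export
classify_hits <- function(hits, domains, sequences = NULL) {
  domains <- check_domain_table(domains)
  if (!is.null(sequences)) {
    sequences <- check_sequences(sequences)
    len <- nchar(sequences)[hits$sequence_id]
    bad <- which(is.na(len) | hits$start < 0 | hits$end > len)
    if (length(bad))
      stop("hit interval(s) outside sequence bounds for: ",
           paste(unique(hits$sequence_id[bad]), collapse = ", "),
           call. = FALSE)
  }
  n <- nrow(hits)
  label <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    d <- domains[domains$protein_id == hits$sequence_id[k] &
                 domains$start <= hits$start[k] &
                 domains$end >= hits$end[k], , drop = FALSE]
    if (nrow(d)) label[k] <- d$domain_label[1L]
  }
  intra <- hits[!is.na(label), , drop = FALSE]
  if (nrow(intra)) intra$domain_label <- label[!is.na(label)]
  else intra$domain_label <- character(0)
  extra <- hits[is.na(label), , drop = FALSE]
  rownames(intra) <- rownames(extra) <- NULL

  per_domain <- if (nrow(intra)) {
    agg <- stats::aggregate(list(n_hits = intra$start),
                            by = list(protein_id = intra$sequence_id,
                                      domain_label = intra$domain_label),
                            FUN = length)
    agg[order(agg$protein_id, agg$domain_label), , drop = FALSE]
  } else data.frame(protein_id = character(0), domain_label = character(0),
                    n_hits = integer(0))
  per_protein <- if (nrow(intra)) {
    agg <- stats::aggregate(list(n_intra = intra$start),
                            by = list(protein_id = intra$sequence_id),
                            FUN = length)
    agg[order(agg$protein_id), , drop = FALSE]
  } else data.frame(protein_id = character(0), n_intra = integer(0))
  rownames(per_domain) <- rownames(per_protein) <- NULL

  structure(list(
    intra = intra, extra = extra,
    per_domain = per_domain, per_protein = per_protein,
    n_domains_with_hit = nrow(per_domain),
    n_proteins_with_hit = nrow(per_protein),
    total = n), class = "hit_classification")
}

#' @export
print.hit_classification <- function(x, ...) {
  cat("Hit classification:", x$total, "hits =",
      nrow(x$intra), "intra-domain +", nrow(x$extra), "extra-domain\n")
  cat("  domains with >=1 hit:", x$n_domains_with_hit,
      " proteins with >=1 intra hit:", x$n_proteins_with_hit, "\n")
  invisible(x)
}

check_domain_table <- function(domains) {
  req <- c("protein_id", "domain_label", "start", "end")
  if (!is.data.frame(domains) || !all(req %in% names(domains)))
    stop("domain table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(domains$start >= domains$end))
    stop("domain intervals must satisfy start < end", call. = FALSE)
  for (pid in unique(domains$protein_id)) {
    d <- domains[domains$protein_id == pid, , drop = FALSE]
    if (anyDuplicated(d$domain_label))
      stop("duplicate domain label for protein ", pid, call. = FALSE)
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping domain intervals for protein ", pid, call. = FALSE)
  }
  domains
}

#' Extract flanked insert records around motif hits
#'
#' For every hit, emits the matched core padded with up to `flank` residues
#' of sequence context on each side; positions beyond the sequence ends are
#' filled with `-`, so all flanked strings of equal-span hits have equal
#' length (the x-x-x-core-x-x-x records behind a sequence logo).
#'
#' @inheritParams classify_hits
#' @param sequences named character vector containing every hit's sequence.
#' @param flank number of context residues on each side (default 3).
#' @param domains optional domain table; when given, each record carries the
#'   containing domain's label (NA for extra-domain hits).
#' @return A data frame with columns `protein_id`, `domain_label`, `start`,
#'   `end`, `core`, `flanked`, `left_pad`, `right_pad`.
#' @export
extract_flanked_inserts <- function(hits, sequences, flank = 3L,
                                    domains = NULL) {
  sequences <- check_sequences(sequences)
  flank <- as.integer(flank)
  stopifnot(flank >= 0L)
  len <- nchar(sequences)[hits$sequence_id]
  if (any(is.na(len) | hits$start < 0 | hits$end > len))
    stop("hit interval(s) outside sequence bounds", call. = FALSE)

  label <- rep(NA_character_, nrow(hits))
  if (!is.null(domains)) {
    cls <- classify_hits(hits, domains)
    key <- paste(hits$sequence_id, hits$start, hits$end)
    ikey <- paste(cls$intra$sequence_id, cls$intra$start, cls$intra$end)
    label[match(ikey, key)] <- cls$intra$domain_label
  }

  n <- nrow(hits)
  core <- flanked <- character(n)
  lpad <- rpad <- integer(n)
  for (k in seq_len(n)) {
    s <- sequences[[hits$sequence_id[k]]]
    a <- hits$start[k]; b <- hits$end[k]; L <- nchar(s)
    core[k] <- substring(s, a + 1L, b)
    left_avail <- min(flank, a)
    right_avail <- min(flank, L - b)
    left <- substring(s, a - left_avail + 1L, a)
    right <- substring(s, b + 1L, b + right_avail)
    lpad[k] <- left_avail
    rpad[k] <- right_avail
    flanked[k] <- paste0(strrep("-", flank - left_avail), left, core[k],
                         right, strrep("-", flank - right_avail))
  }
  data.frame(protein_id = hits$sequence_id, domain_label = label,
             start = hits$start, end = hits$end,
             core = core, flanked = flanked,
             left_pad = lpad, right_pad = rpad,
             stringsAsFactors = FALSE)
}

## column residue-frequency matrix (20 x L) over standard residues;
## gaps and non-standard letters are excluded per column
column_frequencies <- function(cores) {
  if (!length(cores)) stop("no insert records", call. = FALSE)
  w <- unique(nchar(cores))
  if (length(w) != 1L)
    stop("insert cores have unequal lengths: ",
         paste(w, collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(cores), ""))
  freq <- matrix(0, nrow = 20L, ncol = w,
                 dimnames = list(AA_STANDARD, NULL))
  for (j in seq_len(w)) {
    counts <- table(factor(mat[, j], levels = AA_STANDARD))
    tot <- sum(counts)
    if (tot == 0L)
      stop("column ", j, " has no standard residues", call. = FALSE)
    freq[, j] <- as.numeric(counts) / tot
  }
  freq
}

#' Derive a PROSITE-style consensus from aligned insert cores
#'
#' Column rule: if the most frequent residue reaches `single_threshold` and
#' the runner-up stays below `1 - single_threshold`, the column is written
#' as that residue; otherwise, if the top two residues jointly reach
#' `pair_threshold`, as the two-letter class `[XY]` (alphabetical);
#' otherwise as the wildcard `x`. The defaults (0.5 / 0.75) make a 50/50
#' split at a column come out as a two-letter class while a clear majority
#' stays a single letter — e.g. an Ala column that acquires Thr in half of
#' an enlarged record set turns from `A` into `[AT]`.
#'
#' @param cores character vector of equal-length motif cores (or a record
#'   data frame from [extract_flanked_inserts()], whose `core` column is used).
#' @param single_threshold minimum frequency for a single-residue column.
#' @param pair_threshold minimum joint frequency for a two-residue class.
#' @return An object of class `consensus_profile`: list with `freq`
#'   (20 x L column frequency matrix), `ic` (per-column information content,
#'   bits), `consensus` (PROSITE-syntax string) and `n` (number of records).
#' @export
build_consensus <- function(cores, single_threshold = 0.5,
                            pair_threshold = 0.75) {
  if (is.data.frame(cores)) cores <- cores$core
  stopifnot(single_threshold > 0, single_threshold <= 1,
            pair_threshold > 0, pair_threshold <= 1)
  freq <- column_frequencies(cores)
  tokens <- character(ncol(freq))
  for (j in seq_len(ncol(freq))) {
    f <- sort(freq[, j], decreasing = TRUE)
    if (f[1L] >= single_threshold && f[2L] < (1 - single_threshold)) {
      tokens[j] <- names(f)[1L]
    } else if (f[1L] + f[2L] >= pair_threshold) {
      tokens[j] <- paste0("[", paste(sort(names(f)[1:2]), collapse = ""), "]")
    } else {
      tokens[j] <- "x"
    }
  }
  structure(list(freq = freq,
                 ic = ic_from_frequencies(freq),
                 consensus = paste(tokens, collapse = "-"),
                 n = length(cores)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("Consensus over", x$n, "records:", x$consensus, "\n")
  cat("  per-column IC (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

ic_from_frequencies <- function(freq, n = NULL, correction = "none") {
  H <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  if (correction == "miller-madow") {
    k <- apply(freq, 2L, function(f) sum(f > 0))
    H <- H + (k - 1) / (2 * n * log(2))
  }
  pmin(pmax(log2(20) - H, 0), log2(20))
}

#' Per-column information content of aligned insert cores
#'
#' The height of a sequence-logo column: `log2(20) - H_j`, with `H_j` the
#' Shannon entropy (bits) of column j's residue frequencies. No small-sample
#' correction is applied by default; `correction = "miller-madow"` adds the
#' first-order entropy bias correction `(k - 1) / (2 n ln 2)` used by common
#' logo renderers.
#'
#' @inheritParams build_consensus
#' @param correction `"none"` (default) or `"miller-madow"`.
#' @return Numeric vector of per-column IC values in `[0, log2(20)]` bits.
#' @export
information_content <- function(cores, correction = c("none", "miller-madow")) {
  if (is.data.frame(cores)) cores <- cores$core
  correction <- match.arg(correction)
  freq <- column_frequencies(cores)
  ic_from_frequencies(freq, n = length(cores), correction = correction)
}

#' Detect insertion segments in a multiple sequence alignment
#'
#' A column is an insert column iff its gap fraction is at least
#' `gap_fraction_threshold`; maximal runs of at least `min_run` consecutive
#' insert columns are reported, together with the ids of the rows that carry
#' at least 50% residues (non-gaps) within the run — the lineages bearing
#' the insertion.
#'
#' @param msa named character vector of aligned rows (equal lengths; gaps
#'   `-`, with `.` accepted and normalized).
#' @param gap_fraction_threshold minimum per-column gap fraction (default 0.5).
#' @param min_run minimum run length in columns (default 4).
#' @return A data frame with 0-based half-open `start`/`end` column
#'   coordinates, `n_members`, and a list-column `members` of row ids.
#' @export
detect_msa_insertions <- function(msa, gap_fraction_threshold = 0.5,
                                  min_run = 4L) {
  msa <- check_alignment(msa)
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)
  gapfrac <- colMeans(mat == "-")
  is_insert <- gapfrac >= gap_fraction_threshold
  runs <- rle(is_insert)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_run)
  out <- lapply(keep, function(i) {
    cols <- starts[i]:ends[i]
    resid_frac <- rowMeans(mat[, cols, drop = FALSE] != "-")
    members <- names(msa)[resid_frac >= 0.5]
    data.frame(start = starts[i] - 1L, end = ends[i],
               n_members = length(members),
               members = I(list(members)), stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      n_members = integer(0), members = I(list())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_alignment <- function(msa) {
  msa <- check_sequences(msa, allow_gaps = TRUE)
  msa <- chartr(".", "-", msa)
  w <- nchar(msa)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: row(s) ",
         paste(names(msa)[w != w[1L]], collapse = ", "),
         " differ in length", call. = FALSE)
  msa
}
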