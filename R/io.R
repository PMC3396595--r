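#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings with the package's validation rules: ids
#' (first whitespace-delimited header token) must be unique, residues
#' alphabetic; wrapped and unwrapped line layouts and CRLF line endings
#' parse identically. Sequences are uppercased on ingest.
#'
#' @param path FASTA file path.
#' @return [read_fasta()] returns a named character vector of sequences,
#'   with header remainders in the `descriptions` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- stats::setNames(as.character(set), ids)
  seqs <- check_sequences(seqs)
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' @rdname read_fasta
#' @param sequences named character vector (optionally carrying a
#'   `descriptions` attribute).
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  sequences <- check_sequences(sequences, allow_gaps = TRUE)
  desc <- attr(sequences, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    d <- if (!is.null(desc) && nzchar(desc[[id]] %||% "")) paste0(" ", desc[[id]]) else ""
    writeLines(paste0(">", id, d), con)
    s <- sequences[[id]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Clustal format; `.` gaps are normalized to `-`
#' and ragged alignments are rejected with the offending row named.
#'
#' @param path alignment file.
#' @param dialect `"aligned-fasta"` (default) or `"clustal"`.
#' @return Named character vector of aligned rows.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  msa <- if (dialect == "aligned-fasta") read_fasta_gapped(path)
         else read_clustal(path)
  check_alignment(msa)
}

## Minimal Clustal reader: a CLUSTAL header line, then one or more blocks of
## "name  segment [column]" rows; conservation lines (leading whitespace)
## and blank lines are skipped, segments are concatenated per name.
read_clustal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1L]))
    stop("not a Clustal file (missing CLUSTAL header): ", path,
         call. = FALSE)
  segs <- list()
  for (ln in lines[-1L]) {
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next
    m <- regmatches(ln, regexec(
      "^(\\S+)\\s+([A-Za-z.~-]+)(\\s+\\d+)?\\s*$", ln))[[1L]]
    if (length(m) == 0L)
      stop("unparseable Clustal line: ", ln, call. = FALSE)
    segs[[m[2L]]] <- c(segs[[m[2L]]], m[3L])
  }
  if (!length(segs)) stop("no sequences in Clustal file: ", path,
                          call. = FALSE)
  toupper(vapply(segs, paste, "", collapse = ""))
}

read_fasta_gapped <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  check_sequences(stats::setNames(as.character(set), ids), allow_gaps = TRUE)
}

#' Write a tree in Newick format
#'
#' Branch lengths are retained and bootstrap supports (the tree's
#' `node.label`) are written as internal-node labels. A round trip through
#' [read_newick()] preserves topology, labels and branch lengths.
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read / write a domain interval table
#'
#' TSV with columns `protein_id`, `domain_label`, `start`, `end`, 0-based
#' half-open; `#` comment lines ignored.
#'
#' @param path file path.
#' @return A validated domain table data frame.
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("protein_id", "domain_label",
                                         "start", "end"),
                           colClasses = c("character", "character",
                                          "integer", "integer"),
                           stringsAsFactors = FALSE)
  check_domain_table(tab)
}

#' @rdname read_domain_table
#' @param domains domain table data frame.
#' @param header_comment optional `#` comment line(s) written first.
#' @export
write_domain_table <- function(domains, path, header_comment = NULL) {
  domains <- check_domain_table(domains)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(domains[, c("protein_id", "domain_label", "start", "end")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a motif configuration file
#'
#' Plain text, one `name<TAB>pattern` per line, `#` comments. The package
#' ships a pre-populated set of calcium-binding motif signatures — the
#' PERCAL consensus, its stringency ladder from the relaxed
#' `G-x-D-x(6)-[DE]-[DE]` down to `G-x-D-G-x(2)-G-T-A-D-D`, the
#' database-screen variants, and classic signatures such as the
#' hemolysin-type calcium-binding region — under
#' `system.file("extdata", "ca_binding_motifs.tsv", package = "percal")`.
#'
#' @param path motif file; defaults to the bundled set.
#' @return A named list of `prosite_pattern` objects.
#' @examples
#' motifs <- read_motifs()
#' names(motifs)
#' @export
read_motifs <- function(path = system.file("extdata", "ca_binding_motifs.tsv",
                                           package = "percal")) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("motif file contains no motifs: ", path,
                           call. = FALSE)
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed motif line(s) ", paste(bad, collapse = ", "),
         " in ", path, call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate motif names in ", path, call. = FALSE)
  pats <- Map(function(n, p) parse_prosite(p, name = n),
              nm, vapply(parts, `[[`, "", 2L))
  stats::setNames(pats, nm)
}

#' Write a hit table as TSV
#'
#' Columns `sequence_id`, `pattern_name`, `start`, `end`, `matched`
#' (0-based half-open coordinates), preceded by `#` header comments
#' recording tool version, configuration hash and seed.
#'
#' @param hits hit data frame.
#' @param path output path.
#' @param comment named character vector folded into the header comments.
#' @export
write_hits_tsv <- function(hits, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header_comments(con, comment)
  utils::write.table(hits[, c("sequence_id", "pattern_name", "start",
                              "end", "matched")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_header_comments <- function(con, comment) {
  base <- c(tool = paste0("percal ", as.character(
    utils::packageVersion("percal"))))
  all_c <- c(base, comment)
  writeLines(sprintf("# %s=%s", names(all_c), unname(all_c)), con)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with the package defaults.
#' Paths may be NULL when the corresponding stage is skipped.
#'
#' @param sequences path to a FASTA of protein or domain sequences.
#' @param motifs path to a motif file (default: bundled set), or a named
#'   character vector of pattern strings.
#' @param domains optional path to a domain interval TSV.
#' @param alignment optional path to an alignment (for the tree stage).
#' @param policy overlap policy for scanning.
#' @param background `"auto"` (estimate from the scanned collection) or a
#'   path to a composition TSV.
#' @param flank flank width for insert extraction.
#' @param single_threshold,pair_threshold consensus thresholds.
#' @param gap_fraction,min_run alignment insertion-detection thresholds.
#' @param reps bootstrap replicates for the tree stage.
#' @param model distance model for the tree stage.
#' @param seed RNG seed recorded in all outputs.
#' @param out output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sequences, motifs = NULL, domains = NULL,
                       alignment = NULL,
                       policy = c("all-starts", "non-overlapping-leftmost"),
                       background = "auto", flank = 3L,
                       single_threshold = 0.5, pair_threshold = 0.75,
                       gap_fraction = 0.5, min_run = 4L,
                       reps = 500L, model = "poisson-corrected",
                       seed = 1L, out = tempfile("percal_run_")) {
  structure(list(
    sequences = sequences, motifs = motifs, domains = domains,
    alignment = alignment, policy = match.arg(policy),
    background = background, flank = as.integer(flank),
    single_threshold = single_threshold, pair_threshold = pair_threshold,
    gap_fraction = gap_fraction, min_run = as.integer(min_run),
    reps = as.integer(reps), model = model,
    seed = as.integer(seed), out = out), class = "run_config")
}

#' Run the full motif-discovery pipeline
#'
#' Executes scan, intra/extra classification, flanked-insert extraction,
#' consensus and information content, observed/expected enrichment, and
#' (when an alignment is supplied) insertion detection plus a bootstrap
#' neighbor-joining tree. Every output file carries header comments with
#' the tool version, a hash of the configuration and the seed; re-running
#' an identical configuration yields byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a result list: `hits`, `classification`, `inserts`,
#'   `consensus` (per motif with intra-domain hits), `enrichment`,
#'   `insertions` and `tree` (NULL when skipped), plus `paths` of the files
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  ## the output directory is where results land, not an analysis parameter
  hashed <- unclass(config)
  hashed$out <- NULL
  chash <- config_hash(lapply(hashed, function(x) if (is.null(x)) NA else x))
  hdr <- c(config_hash = chash, seed = as.character(config$seed))

  sequences <- if (is.character(config$sequences) &&
                   length(config$sequences) == 1L &&
                   file.exists(config$sequences))
    read_fasta(config$sequences) else check_sequences(config$sequences)

  motifs <- if (is.null(config$motifs)) read_motifs()
    else if (is.list(config$motifs)) config$motifs
    else if (length(config$motifs) == 1L && is.null(names(config$motifs)) &&
             file.exists(config$motifs)) read_motifs(config$motifs)
    else Map(parse_prosite, config$motifs,
             names(config$motifs) %||% config$motifs)

  domains <- if (is.null(config$domains)) NULL
    else if (is.data.frame(config$domains)) check_domain_table(config$domains)
    else read_domain_table(config$domains)

  background <- if (identical(config$background, "auto"))
    estimate_background(sequences) else if (inherits(config$background,
                                                     "background_model"))
    config$background else read_background(config$background)

  paths <- list()

  ## scan every motif
  hits <- do.call(rbind, c(lapply(motifs, function(p)
    scan_collection(p, sequences, policy = config$policy)),
    make.row.names = FALSE))
  paths$hits <- file.path(config$out, "hits.tsv")
  write_hits_tsv(hits, paths$hits, hdr)

  ## classify against domains, per motif
  classification <- NULL
  count_table <- NULL
  inserts <- NULL
  consensus <- list()
  if (!is.null(domains)) {
    count_rows <- lapply(names(motifs), function(nm) {
      h <- hits[hits$pattern_name == nm, , drop = FALSE]
      cl <- classify_hits(h, domains, sequences)
      data.frame(motif = nm,
                 intra_hits = nrow(cl$intra),
                 extra_hits = nrow(cl$extra),
                 domains_with_hit = cl$n_domains_with_hit,
                 proteins_with_hit = cl$n_proteins_with_hit,
                 stringsAsFactors = FALSE)
    })
    count_table <- do.call(rbind, c(count_rows, make.row.names = FALSE))
    paths$counts <- file.path(config$out, "domain_counts.tsv")
    con <- file(paths$counts, "w")
    write_header_comments(con, hdr)
    utils::write.table(count_table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    classification <- classify_hits(hits, domains, sequences)

    inserts <- extract_flanked_inserts(classification$intra, sequences,
                                       flank = config$flank,
                                       domains = domains)
    paths$inserts <- file.path(config$out, "inserts.fasta")
    write_insert_fasta(inserts, paths$inserts)

    for (nm in unique(classification$intra$pattern_name)) {
      sub <- classification$intra[classification$intra$pattern_name == nm, ,
                                  drop = FALSE]
      if (length(unique(sub$end - sub$start)) == 1L && nrow(sub) > 0L) {
        consensus[[nm]] <- build_consensus(
          sub$matched,
          single_threshold = config$single_threshold,
          pair_threshold = config$pair_threshold)
      }
    }
    if (length(consensus)) {
      paths$consensus <- file.path(config$out, "consensus.tsv")
      con <- file(paths$consensus, "w")
      write_header_comments(con, hdr)
      for (nm in names(consensus))
        writeLines(paste(nm, consensus[[nm]]$consensus,
                         paste(sprintf("%.4f", consensus[[nm]]$ic),
                               collapse = ","), sep = "\t"), con)
      close(con)
    }
  }

  ## enrichment (Table-5-style report)
  enrichment <- enrichment_table(motifs, sequences, background = background)
  paths$enrichment <- file.path(config$out, "enrichment.tsv")
  con <- file(paths$enrichment, "w")
  write_header_comments(con, hdr)
  utils::write.table(enrichment, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  ## alignment stage
  insertions <- NULL
  tree <- NULL
  if (!is.null(config$alignment)) {
    msa <- if (is.character(config$alignment) &&
               length(config$alignment) == 1L &&
               file.exists(config$alignment))
      read_alignment(config$alignment) else check_alignment(config$alignment)
    insertions <- detect_msa_insertions(msa,
                                        gap_fraction_threshold = config$gap_fraction,
                                        min_run = config$min_run)
    paths$insertions <- file.path(config$out, "msa_insertions.tsv")
    con <- file(paths$insertions, "w")
    write_header_comments(con, hdr)
    if (nrow(insertions))
      writeLines(sprintf("%d\t%d\t%s", insertions$start, insertions$end,
                         vapply(insertions$members, paste, "",
                                collapse = ",")), con)
    close(con)

    tree <- bootstrap_consensus(msa, n_reps = config$reps,
                                seed = config$seed, model = config$model)
    paths$tree <- file.path(config$out, "tree.nwk")
    write_newick(tree, paths$tree)
  }

  invisible(list(hits = hits, classification = classification,
                 count_table = count_table, inserts = inserts,
                 consensus = consensus, enrichment = enrichment,
                 insertions = insertions, tree = tree, paths = paths,
                 config_hash = chash))
}

#' Write / read flanked insert records as FASTA
#'
#' Headers follow the structured form `protein_id|domain_label|start-end`
#' (0-based half-open; `.` for extra-domain records); sequences are the
#' flanked strings with `-` padding.
#'
#' @param inserts insert record data frame from [extract_flanked_inserts()].
#' @param path file path.
#' @export
write_insert_fasta <- function(inserts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(inserts))) {
    lab <- if (is.na(inserts$domain_label[k])) "." else inserts$domain_label[k]
    writeLines(c(sprintf(">%s|%s|%d-%d", inserts$protein_id[k], lab,
                         inserts$start[k], inserts$end[k]),
                 inserts$flanked[k]), con)
  }
  invisible(path)
}

#' @rdname write_insert_fasta
#' @export
read_insert_fasta <- function(path) {
  recs <- read_fasta_gapped(path)
  parts <- strsplit(names(recs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed insert header(s): ",
         paste(names(recs)[bad], collapse = ", "), call. = FALSE)
  iv <- strsplit(vapply(parts, `[[`, "", 3L), "-", fixed = TRUE)
  data.frame(
    protein_id = vapply(parts, `[[`, "", 1L),
    domain_label = ifelse(vapply(parts, `[[`, "", 2L) == ".", NA_character_,
                          vapply(parts, `[[`, "", 2L)),
    start = as.integer(vapply(iv, `[[`, "", 1L)),
    end = as.integer(vapply(iv, `[[`, "", 2L)),
    flanked = unname(recs),
    stringsAsFactors = FALSE)
}
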