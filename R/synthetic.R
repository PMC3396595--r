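#' Generate i.i.d. background protein sequences
#'
#' Draws `n` sequences whose residues are independent samples from a
#' background composition — the null model under which motif enrichment is
#' judged. Bit-reproducible given `seed`; the generator parameters are
#' attached as a `manifest` attribute (see [write_manifest()]).
#'
#' @param n number of sequences.
#' @param lengths sequence length(s); a vector is recycled to length `n`.
#' @param background a `background_model` (default uniform).
#' @param seed RNG seed.
#' @param prefix id prefix (ids are `prefix1 ... prefixN`).
#' @return Named character vector of sequences.
#' @examples
#' generate_background_sequences(2, 12, seed = 1)
#' @export
generate_background_sequences <- function(n, lengths,
                                          background = uniform_background(),
                                          seed = NULL, prefix = "seq") {
  stopifnot(n >= 1, all(lengths >= 1), inherits(background, "background_model"))
  seqs <- with_seed(seed, draw_background(n, lengths, background))
  names(seqs) <- sprintf("%s%d", prefix, seq_len(n))
  attr(seqs, "manifest") <- list(
    generator = "generate_background_sequences",
    n = n, lengths = rep_len(as.integer(lengths), n),
    background = as.list(stats::setNames(as.numeric(background),
                                         names(background))),
    seed = seed)
  seqs
}

#' Specification for planting motif insertions
#'
#' Bundles the parameters of [plant_insertions()]: a per-column residue
#' frequency profile for the motif core, the number of inserts spliced into
#' each designated domain, the domain geometry, and an optional rate of
#' extra-domain inserts.
#'
#' @param profile a 20 x W column-frequency matrix (rows named by residue,
#'   columns summing to 1), or a residue string such as `"GADGAAGTADD"`
#'   for a deterministic (zero-ambiguity) profile.
#' @param inserts_per_domain non-negative integer: inserts spliced into each
#'   domain.
#' @param n_domains domains designated per sequence.
#' @param domain_length integer range `c(min, max)` for domain lengths.
#' @param extra_rate expected number (Poisson) of extra-domain inserts per
#'   sequence.
#' @param flank flank width recorded in the manifest (for downstream
#'   [extract_flanked_inserts()] calls).
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(profile, inserts_per_domain = 5L, n_domains = 2L,
                       domain_length = c(150L, 250L), extra_rate = 0,
                       flank = 3L) {
  if (is.character(profile)) profile <- profile_from_string(profile)
  stopifnot(is.matrix(profile), nrow(profile) == 20L)
  if (is.null(rownames(profile))) rownames(profile) <- AA_STANDARD
  stopifnot(identical(sort(rownames(profile)), AA_STANDARD),
            all(abs(colSums(profile) - 1) < 1e-9),
            all(profile >= 0),
            inserts_per_domain >= 0, n_domains >= 1,
            length(domain_length) == 2L,
            domain_length[1L] <= domain_length[2L],
            extra_rate >= 0)
  structure(list(profile = profile[AA_STANDARD, , drop = FALSE],
                 inserts_per_domain = as.integer(inserts_per_domain),
                 n_domains = as.integer(n_domains),
                 domain_length = as.integer(domain_length),
                 extra_rate = extra_rate, flank = as.integer(flank)),
            class = "plant_spec")
}

#' @rdname plant_spec
#' @param string residue string, one point-mass column per letter.
#' @export
profile_from_string <- function(string) {
  letters_ <- strsplit(toupper(string), "")[[1]]
  bad <- setdiff(letters_, AA_STANDARD)
  if (length(bad))
    stop("profile string contains non-standard letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  prof <- matrix(0, 20L, length(letters_), dimnames = list(AA_STANDARD, NULL))
  prof[cbind(match(letters_, AA_STANDARD), seq_along(letters_))] <- 1
  prof
}

#' @rdname plant_spec
#' @param x_background `background_model` used for the wildcard columns of
#'   the PERCAL consensus profile (default uniform).
#' @details [percal_profile()] builds the 11-column profile of the PERCAL
#'   consensus G-x-D-G-x-x-\[GN\]-\[TN\]-x-D-D: point mass on the fixed
#'   residues, a 50/50 split on the two-letter classes, and `x_background`
#'   on the wildcard columns.
#' @export
percal_profile <- function(x_background = uniform_background()) {
  stopifnot(inherits(x_background, "background_model"))
  bg <- as.numeric(x_background)
  col <- function(tok) {
    if (tok == "x") return(bg)
    f <- numeric(20L)
    letters_ <- strsplit(tok, "")[[1]]
    f[match(letters_, AA_STANDARD)] <- 1 / length(letters_)
    f
  }
  toks <- c("G", "x", "D", "G", "x", "x", "GN", "TN", "x", "D", "D")
  prof <- vapply(toks, col, numeric(20L))
  dimnames(prof) <- list(AA_STANDARD, NULL)
  prof
}

sample_core <- function(profile) {
  paste(vapply(seq_len(ncol(profile)), function(j)
    sample(AA_STANDARD, 1L, prob = profile[, j]), ""), collapse = "")
}

#' Plant motif insertions into background sequences
#'
#' Designates `n_domains` non-overlapping domain intervals per sequence,
#' then splices motif cores sampled from the profile at uniform positions
#' inside each domain (insertions lengthen the sequence; they interrupt it
#' rather than overwrite it) and, optionally, outside the domains at rate
#' `extra_rate`. Domain coordinates are updated for every length change, so
#' each planted intra-domain core is fully contained in its (grown) domain
#' and each extra-domain core is fully outside all domains.
#'
#' @param sequences named character vector of host sequences.
#' @param spec a [plant_spec()].
#' @param seed RNG seed.
#' @return A list with `sequences` (spliced), `domains` (domain table, one
#'   row per designated interval, labels `"A"`, `"B"`, ...), `truth`
#'   (data frame of planted intervals: `protein_id`, `start`, `end`,
#'   `label` intra/extra, `domain_label`, `core`) and a `manifest`
#'   attribute.
#' @export
plant_insertions <- function(sequences, spec, seed = NULL) {
  stopifnot(inherits(spec, "plant_spec"))
  sequences <- check_sequences(sequences)
  W <- ncol(spec$profile)

  out <- with_seed(seed, {
    dom_rows <- list(); truth_rows <- list(); new_seqs <- sequences
    for (sid in names(sequences)) {
      L <- nchar(sequences[[sid]])
      dl <- spec$domain_length[1L] +
        sample.int(spec$domain_length[2L] - spec$domain_length[1L] + 1L,
                   spec$n_domains, replace = TRUE) - 1L
      ## at least one residue between consecutive domains, so planted
      ## boundary insertions can never fuse two domain intervals
      slack <- L - sum(dl) - (spec$n_domains - 1L)
      if (slack < 0)
        stop("sequence ", sid, " too short for ", spec$n_domains,
             " domain(s) of the requested lengths", call. = FALSE)
      if (W > min(dl))
        stop("insert width ", W, " exceeds a designated domain length",
             call. = FALSE)
      ## distribute the remaining slack over the n_domains + 1 gaps
      cuts <- sort(sample.int(slack + 1L, spec$n_domains, replace = TRUE) - 1L)
      starts <- cuts + c(0L, cumsum(dl + 1L))[seq_len(spec$n_domains)]
      ends <- starts + dl
      labels <- LETTERS[seq_len(spec$n_domains)]

      ## choose insertion points (position = residue index before which the
      ## core is spliced); intra points sit inside [start, end] of a domain
      pts <- data.frame(pos = integer(0), dom = character(0),
                        core = character(0), stringsAsFactors = FALSE)
      for (d in seq_len(spec$n_domains)) {
        k <- spec$inserts_per_domain
        if (k > 0L) {
          pos <- starts[d] + sample.int(dl[d] + 1L, k, replace = TRUE) - 1L
          pts <- rbind(pts, data.frame(
            pos = pos, dom = labels[d],
            core = vapply(seq_len(k), function(i) sample_core(spec$profile), ""),
            stringsAsFactors = FALSE))
        }
      }
      n_extra <- if (spec$extra_rate > 0) stats::rpois(1L, spec$extra_rate) else 0L
      if (n_extra > 0L) {
        outside <- setdiff(0:L, unlist(lapply(seq_len(spec$n_domains),
                                              function(d) starts[d]:ends[d])))
        if (length(outside)) {
          pos <- outside[sample.int(length(outside), n_extra, replace = TRUE)]
          pts <- rbind(pts, data.frame(
            pos = pos, dom = NA_character_,
            core = vapply(seq_along(pos),
                          function(i) sample_core(spec$profile), ""),
            stringsAsFactors = FALSE))
        }
      }
      pts <- pts[order(pts$pos), , drop = FALSE]

      ## splice left to right, tracking the cumulative offset
      sq <- sequences[[sid]]
      offset <- 0L
      d_start <- starts; d_end <- ends
      for (r in seq_len(nrow(pts))) {
        p <- pts$pos[r] + offset
        sq <- paste0(substring(sq, 1L, p), pts$core[r],
                     substring(sq, p + 1L))
        ## update domain coordinates: insertions before a domain shift it,
        ## insertions inside extend it
        for (d in seq_len(spec$n_domains)) {
          if (p < d_start[d]) {
            d_start[d] <- d_start[d] + W
            d_end[d] <- d_end[d] + W
          } else if (p <= d_end[d]) {
            d_end[d] <- d_end[d] + W
          }
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          protein_id = sid, start = p, end = p + W,
          label = if (is.na(pts$dom[r])) "extra" else "intra",
          domain_label = pts$dom[r], core = pts$core[r],
          stringsAsFactors = FALSE)
        offset <- offset + W
      }
      new_seqs[[sid]] <- sq
      dom_rows[[sid]] <- data.frame(
        protein_id = sid, domain_label = labels,
        start = d_start, end = d_end, stringsAsFactors = FALSE)
    }
    list(sequences = new_seqs,
         domains = do.call(rbind, c(dom_rows, make.row.names = FALSE)),
         truth = if (length(truth_rows))
           do.call(rbind, c(truth_rows, make.row.names = FALSE))
         else data.frame(protein_id = character(0), start = integer(0),
                         end = integer(0), label = character(0),
                         domain_label = character(0), core = character(0)))
  })
  attr(out, "manifest") <- list(
    generator = "plant_insertions",
    n_sequences = length(sequences),
    insert_width = W,
    inserts_per_domain = spec$inserts_per_domain,
    n_domains = spec$n_domains,
    domain_length = spec$domain_length,
    extra_rate = spec$extra_rate,
    flank = spec$flank,
    seed = seed)
  out
}

#' Evolve a gapless alignment along a tree
#'
#' Simulates amino-acid sequences down a tree under the simplest
#' exchangeability-free model: the root is drawn uniformly over the 20
#' residues; along a branch of length `b` (expected substitutions per site)
#' each site substitutes with probability `1 - exp(-b)` to a uniformly
#' chosen different residue. Leaves are returned as a gapless alignment.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param root_length alignment length (>= 10).
#' @param seed RNG seed.
#' @return Named character vector of aligned leaf sequences, with a
#'   `manifest` attribute.
#' @export
evolve_alignment <- function(tree, root_length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), root_length >= 10)
  L <- as.integer(root_length)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tree_pre <- ape::reorder.phylo(tree, "cladewise")

  msa <- with_seed(seed, {
    seqs <- matrix(NA_integer_, nrow = ntip + nnode, ncol = L)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(20L, L, replace = TRUE)
    for (e in seq_len(nrow(tree_pre$edge))) {
      parent <- tree_pre$edge[e, 1L]
      child <- tree_pre$edge[e, 2L]
      b <- tree_pre$edge.length[e]
      x <- seqs[parent, ]
      mut <- stats::runif(L) < (1 - exp(-b))
      if (any(mut)) {
        shift <- sample.int(19L, sum(mut), replace = TRUE)
        x[mut] <- ((x[mut] - 1L + shift) %% 20L) + 1L
      }
      seqs[child, ] <- x
    }
    leaves <- vapply(seq_len(ntip), function(i)
      paste(AA_STANDARD[seqs[i, ]], collapse = ""), "")
    stats::setNames(leaves, tree_pre$tip.label)
  })
  attr(msa, "manifest") <- list(
    generator = "evolve_alignment",
    tree = ape::write.tree(tree),
    root_length = L, seed = seed)
  msa
}

#' Write a generator manifest as JSON
#'
#' Serializes the `manifest` attribute that every synthetic-data generator
#' attaches to its output (generator name, parameters, seed) to a sidecar
#' JSON file, so a synthetic dataset on disk is self-describing.
#'
#' @param x an object produced by one of the generators.
#' @param path output path.
#' @export
write_manifest <- function(x, path) {
  manifest <- attr(x, "manifest")
  if (is.null(manifest)) stop("object carries no manifest", call. = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
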