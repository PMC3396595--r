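#' Pairwise distances from a protein alignment
#'
#' Computes the proportion of differing residues (p-distance) for every pair
#' of rows, optionally Poisson-corrected as `d = -ln(1 - p)`. Under
#' `pairwise-deletion` each pair is compared over the sites where both rows
#' carry a residue; under `complete-deletion` columns containing any gap are
#' discarded first.
#'
#' @param msa named character vector of aligned rows (equal lengths).
#' @param model `"p-distance"` or `"poisson-corrected"`.
#' @param gap_policy `"pairwise-deletion"` (default) or `"complete-deletion"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by row ids.
#' @examples
#' pairwise_distance(c(a = "AAAA", b = "AAAT"))["a", "b"]  # 0.25
#' @export
pairwise_distance <- function(msa,
                              model = c("p-distance", "poisson-corrected"),
                              gap_policy = c("pairwise-deletion",
                                             "complete-deletion")) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  msa <- check_alignment(msa)
  if (length(msa) < 2L) stop("need at least 2 rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)
  if (gap_policy == "complete-deletion") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      ncomp <- sum(ok)
      if (ncomp == 0L)
        stop("zero comparable sites for pair ", rownames(mat)[i], " / ",
             rownames(mat)[j], call. = FALSE)
      p <- sum(mat[i, ok] != mat[j, ok]) / ncomp
      if (model == "poisson-corrected") {
        if (p >= 1)
          stop("p-distance of 1 for pair ", rownames(mat)[i], " / ",
               rownames(mat)[j], " cannot be Poisson-corrected",
               call. = FALSE)
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining (Saitou & Nei): at each step the
#' pair minimizing the Q-criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, branch
#' lengths follow the standard formulas, and the matrix is reduced. For
#' determinism, ties in Q are broken by the smallest (row, column) index
#' pair in the current label order; negative branch lengths are clamped to
#' zero with the deficit transferred to the sister branch. The result is an
#' unrooted tree (trifurcating root node in the `phylo` encoding).
#'
#' @param D symmetric distance matrix with unique dimnames (or a
#'   [stats::dist] object).
#' @return An [ape::ape-package] `phylo` tree.
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(D)
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  labels <- rownames(D) %||% colnames(D)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix must carry unique labels", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0) || any(D < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)

  ## each active node is carried as a growing newick fragment
  frag <- sprintf("'%s'", gsub("'", "_", labels))
  plain <- !grepl("[ \\(\\):;,\\[\\]']", labels)
  frag[plain] <- labels[plain]

  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ## smallest (row, column) pair among the minima, row-major
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]

    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)

    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    nm <- c(rownames(D)[keep], sprintf("node%d", n))
    dimnames(D2) <- list(nm, nm)
    D <- D2
    n <- n - 1L
  }
  ## final trifurcation: three-point formulas
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- c(v1, v2, v3)
  for (k in 1:3) {
    if (v[k] < 0) {
      sib <- if (k < 3L) k + 1L else 1L
      v[sib] <- v[sib] + v[k]
      v[k] <- 0
    }
  }
  v <- pmax(v, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(v[1]), frag[2], fmt(v[2]), frag[3], fmt(v[3]))
  ape::read.tree(text = nwk)
}

#' Bootstrap-consensus neighbor-joining tree from an alignment
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds a
#' neighbor-joining tree per replicate, and reports either the >= 50%
#' majority-rule consensus (default) or the full-alignment tree, in both
#' cases decorated with bootstrap supports: the percentage of replicates
#' containing each internal bipartition. Replicates whose distance matrix is
#' undefined (a pair with no comparable sites, or a saturated
#' Poisson-corrected pair) are dropped with a warning; if more than 10% are
#' dropped the run aborts.
#'
#' @inheritParams pairwise_distance
#' @param n_reps number of bootstrap replicates (default 500).
#' @param seed RNG seed for the column resampling.
#' @param consensus_rule `"majority"` (>= 50% majority-rule consensus tree)
#'   or `"original"` (neighbor-joining tree of the unresampled alignment,
#'   annotated with supports).
#' @return A `phylo` tree whose `node.label` holds bootstrap supports in
#'   percent (empty for the root).
#' @export
bootstrap_consensus <- function(msa, n_reps = 500L, seed = NULL,
                                model = c("p-distance", "poisson-corrected"),
                                gap_policy = c("pairwise-deletion",
                                               "complete-deletion"),
                                consensus_rule = c("majority", "original")) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  consensus_rule <- match.arg(consensus_rule)
  stopifnot(n_reps >= 1)
  msa <- check_alignment(msa)
  width <- nchar(msa[[1L]])
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)

  trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(width, width, replace = TRUE)
      rep_msa <- stats::setNames(
        apply(mat[, cols, drop = FALSE], 1L, paste, collapse = ""),
        names(msa))
      tryCatch(
        neighbor_joining(pairwise_distance(rep_msa, model = model,
                                           gap_policy = gap_policy)),
        error = function(e) NULL)
    })
  })
  dropped <- sum(vapply(trees, is.null, TRUE))
  if (dropped > 0)
    warning(dropped, " bootstrap replicate(s) dropped (undefined distances)")
  if (dropped > 0.1 * n_reps)
    stop("more than 10% of bootstrap replicates dropped (",
         dropped, "/", n_reps, ")", call. = FALSE)
  trees <- Filter(Negate(is.null), trees)
  n_kept <- length(trees)

  all_tips <- sort(names(msa))
  key_tab <- split_frequencies(trees, all_tips)

  base_tree <- if (consensus_rule == "majority") {
    ape::consensus(trees, p = 0.5)
  } else {
    neighbor_joining(pairwise_distance(msa, model = model,
                                       gap_policy = gap_policy))
  }
  keys <- node_split_keys(base_tree, all_tips)
  support <- vapply(keys, function(k)
    if (is.na(k) || !(k %in% names(key_tab))) 0
    else 100 * key_tab[[k]] / n_kept, 0)
  base_tree$node.label <- as.character(round(support, 1))
  base_tree$node.label[is.na(keys)] <- ""  # trivial splits carry no support
  attr(base_tree, "n_replicates") <- n_kept
  base_tree
}

## canonical key for the bipartition separating `tips` from the rest:
## the side not containing the reference (alphabetically first) tip,
## sorted and joined; NA for trivial splits
canonical_split <- function(tips, all_tips) {
  if (all_tips[1L] %in% tips) tips <- setdiff(all_tips, tips)
  if (length(tips) < 2L || length(tips) > length(all_tips) - 2L)
    return(NA_character_)
  paste(sort(tips), collapse = "|")
}

## one key per internal node (in node order), NA for the root / trivial
node_split_keys <- function(tree, all_tips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(pp, function(ix) canonical_split(labs[ix], all_tips), "")
}

split_frequencies <- function(trees, all_tips) {
  keys <- unlist(lapply(trees, function(tr) {
    k <- node_split_keys(tr, all_tips)
    unique(k[!is.na(k)])
  }))
  table(keys)
}

#' Bootstrap support of one bipartition
#'
#' Fraction (in percent) of the trees that contain the bipartition
#' separating `tips` from the remaining leaves.
#'
#' @param trees a list of `phylo` trees (e.g. bootstrap replicates).
#' @param tips character vector of tip labels on one side of the split.
#' @return Support in percent.
#' @export
split_support <- function(trees, tips) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  all_tips <- sort(trees[[1L]]$tip.label)
  key <- canonical_split(tips, all_tips)
  if (is.na(key)) stop("trivial bipartition", call. = FALSE)
  tab <- split_frequencies(trees, all_tips)
  100 * unname(if (key %in% names(tab)) tab[[key]] else 0) / length(trees)
}

#' Are two leaves sisters (a cherry)?
#'
#' True iff the two leaves attach to a common node that has no other leaf
#' neighbour, judged on the unrooted tree (any degree-2 root is suppressed
#' first). In the degenerate unrooted trees with three or fewer leaves every
#' pair is adjacent to the single internal node, and every pair is reported
#' as sisters.
#'
#' @param tree a `phylo` tree.
#' @param leaf_a,leaf_b tip labels.
#' @return Logical scalar.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' are_sister(tr, "A", "B")  # TRUE
#' are_sister(tr, "A", "C")  # FALSE
#' @export
are_sister <- function(tree, leaf_a, leaf_b) {
  stopifnot(inherits(tree, "phylo"))
  missing_ <- setdiff(c(leaf_a, leaf_b), tree$tip.label)
  if (length(missing_))
    stop("leaf (leaves) not in tree: ", paste(missing_, collapse = ", "),
         call. = FALSE)
  if (leaf_a == leaf_b) return(FALSE)
  if (length(tree$tip.label) <= 3L) return(TRUE)
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  ia <- match(leaf_a, tree$tip.label)
  ib <- match(leaf_b, tree$tip.label)
  pa <- tree$edge[tree$edge[, 2L] == ia, 1L]
  pb <- tree$edge[tree$edge[, 2L] == ib, 1L]
  if (pa != pb) return(FALSE)
  tip_children <- tree$edge[tree$edge[, 1L] == pa, 2L]
  sum(tip_children <= ntip) == 2L
}
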