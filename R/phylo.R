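# Phylogenetics: pairwise/progressive alignment surfaces, maximum-likelihood
# pairwise distances under the JTT model, neighbor-joining trees and
# bootstrap support.

#' Global pairwise alignment of two protein sequences
#'
#' @param a,b Amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix_name Substitution matrix name (e.g. `"BLOSUM62"`), or `NULL`
#'   to use a simple match/mismatch scheme.
#' @param match,mismatch Scores used when `matrix_name` is `NULL`.
#' @return List: `a_aligned`, `b_aligned` (gapped strings), `score`.
#' @export
pairwise_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                           matrix_name = "BLOSUM62", match = 1, mismatch = 0) {
  if (is.null(matrix_name)) {
    letters20 <- unique(c(seq_chars(a), seq_chars(b), AA20))
    sm <- matrix(mismatch, length(letters20), length(letters20),
                 dimnames = list(letters20, letters20))
    diag(sm) <- match
  } else sm <- matrix_name
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  list(a_aligned = as.character(Biostrings::alignedPattern(al)),
       b_aligned = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Progressive multiple sequence alignment
#'
#' Thin surface over the MAFFT progressive aligner (bundled with the
#' runtime environment); input order does not affect the result beyond
#' MAFFT's own deterministic behaviour.
#'
#' @param seqs Named character vector of amino-acid sequences (>= 1).
#' @return Named character vector of equal-length gapped rows, in input
#'   order.
#' @export
align_sequences <- function(seqs) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) return(seqs)
  if (Sys.which("mafft") == "")
    stop("mafft not found on PATH; required for multiple alignment")
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".aln")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  # protect arbitrary labels
  ids <- paste0("s", seq_along(seqs))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(unname(seqs), ids)), fin)
  status <- system2("mafft", c("--quiet", "--auto", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  out <- Biostrings::readAAStringSet(fout)
  aligned <- toupper(as.character(out))
  names(aligned) <- names(seqs)[match(sub("\\s.*", "", names(out)), ids)]
  aligned[names(seqs)]
}

encode_alignment <- function(rows, model = jtt_model()) {
  L <- unique(nchar(rows))
  if (length(L) != 1) stop("alignment rows differ in length")
  mat <- vapply(rows, function(r) match(seq_chars(r), model$aa),
                integer(L))
  t(mat)  # taxa x columns, NA for gaps/unknowns
}

jtt_pair_counts <- function(xi, xj) {
  keep <- !is.na(xi) & !is.na(xj)
  if (!any(keep)) return(NULL)
  matrix(tabulate((xi[keep] - 1L) * 20L + xj[keep], nbins = 400L),
         20, 20, byrow = TRUE)
}

jtt_mldist_counts <- function(N, model, max_dist) {
  if (sum(N) == 0) stop("no shared ungapped columns")
  if (sum(N * (1 - diag(20))) == 0) return(0)
  logpi <- log(model$freq)
  nll <- function(t) {
    P <- jtt_prob(t, model)
    -sum(N * (logpi + log(P)))
  }
  opt <- stats::optimize(nll, c(1e-7, max_dist), tol = 1e-8)
  d <- opt$minimum
  if (d > max_dist * 0.99) {
    attr(d, "saturated") <- TRUE
    d <- structure(max_dist, saturated = TRUE)
  }
  d
}

#' Maximum-likelihood JTT distance between two aligned sequences
#'
#' One-dimensional likelihood maximisation over branch length under the JTT
#' substitution model with equal rates across sites; gapped columns are
#' removed pairwise. Distances that run into the upper bound are capped and
#' flagged with attribute `saturated`.
#'
#' @param row_i,row_j Equal-length gapped amino-acid strings.
#' @param max_dist Saturation cap (expected substitutions per site).
#' @return Nonnegative distance; exactly 0 iff the rows agree on every
#'   shared ungapped column.
#' @export
jtt_distance <- function(row_i, row_j, max_dist = 10) {
  model <- jtt_model()
  enc <- encode_alignment(c(a = row_i, b = row_j), model)
  N <- jtt_pair_counts(enc[1, ], enc[2, ])
  if (is.null(N)) stop("no shared ungapped columns")
  jtt_mldist_counts(N, model, max_dist)
}

#' JTT distance matrix of an alignment
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param max_dist Saturation cap per pair.
#' @return Symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
jtt_dist_matrix <- function(aln, max_dist = 10) {
  model <- jtt_model()
  enc <- encode_alignment(aln, model)
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    N <- jtt_pair_counts(enc[i, ], enc[j, ])
    if (is.null(N)) stop("no shared ungapped columns between ",
                         names(aln)[i], " and ", names(aln)[j])
    d[i, j] <- d[j, i] <- as.numeric(jtt_mldist_counts(N, model, max_dist))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape) with taxa pre-sorted by label so that
#' tie-breaking is input-order independent; negative branch lengths are
#' clamped to zero and flagged with attribute `clamped`.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining requires at least 3 taxa")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tr <- ape::nj(stats::as.dist(dm))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds a JTT-distance NJ
#' tree per replicate, and annotates each internal node of the point
#' estimate with the percentage of replicates containing its bipartition.
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param n_reps Number of bootstrap replicates.
#' @param seed RNG seed (resampling is reproducible given the seed).
#' @param max_dist Saturation cap per pair.
#' @return A `phylo` tree whose `node.label` holds support percentages.
#' @export
bootstrap_tree <- function(aln, n_reps, seed = 1L, max_dist = 10) {
  stopifnot(n_reps >= 1)
  point <- nj_tree(jtt_dist_matrix(aln, max_dist))
  L <- unique(nchar(aln))
  stopifnot(length(L) == 1)
  chars <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(chars) <- names(aln)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      rows <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      nj_tree(jtt_dist_matrix(rows, max_dist))
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  supp <- round(100 * counts / n_reps, 1)
  point$node.label <- ifelse(is.na(supp), "", as.character(supp))
  attr(point, "n_reps") <- n_reps
  point
}

# tip sets of every internal node (index = node id - Ntip)
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[[i]]
  # postorder: edges below a node precede the edge into it
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets[(ntip + 1):(ntip + nnode)]
}

#' Bootstrap support of a tip-set bipartition
#'
#' @param tree A tree from [bootstrap_tree()].
#' @param tips Tip labels forming one side of the bipartition.
#' @return Support percentage, or `NA` when the bipartition is not in the
#'   tree (the tip set is not a clade under any rooting).
#' @export
clade_support <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  sets <- node_tip_sets(ape::reorder.phylo(tree, "postorder"))
  target <- sort(tips)
  comp <- sort(setdiff(tree$tip.label, tips))
  for (i in seq_along(sets)) {
    s <- sort(sets[[i]])
    if (identical(s, target) || identical(s, comp)) {
      lab <- tree$node.label[[i]]
      return(if (is.null(lab) || !nzchar(lab)) NA_real_ else as.numeric(lab))
    }
  }
  NA_real_
}

#' Test whether a tip set is monophyletic (as an unrooted bipartition)
#'
#' @inheritParams clade_support
#' @return Logical.
#' @export
is_split <- function(tree, tips) {
  sets <- node_tip_sets(ape::reorder.phylo(tree, "postorder"))
  target <- sort(tips)
  comp <- sort(setdiff(tree$tip.label, tips))
  any(vapply(sets, function(s) {
    s <- sort(s); identical(s, target) || identical(s, comp)
  }, TRUE))
}
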