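# Alignment primitives, JTT maximum-likelihood distances, neighbor joining
# and bootstrap support, each checked against an independent oracle.

## ---- pairwise alignment ----------------------------------------------------

test_that("self-alignment scores the sum of diagonal substitution values", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  a <- "MKTAYIAKQR"
  al <- pairwise_align(a, a)
  expect_equal(al$a_aligned, a)
  expect_equal(al$score,
               sum(diag(BLOSUM62)[match(strsplit(a, "")[[1]],
                                        rownames(BLOSUM62))]))
})

test_that("simple-scoring alignment matches exhaustive enumeration", {
  al <- pairwise_align("ACD", "AD", gap_open = 0, gap_extend = 1,
                       matrix_name = NULL, match = 1, mismatch = 0)
  expect_equal(al$score, 1)
  expect_equal(al$score, align_score_oracle("ACD", "AD"))
  # a few random short pairs against the oracle
  set.seed(601)
  for (i in 1:10) {
    a <- random_protein(sample(2:6, 1)); b <- random_protein(sample(2:6, 1))
    al <- pairwise_align(a, b, gap_open = 0, gap_extend = 1,
                         matrix_name = NULL, match = 1, mismatch = 0)
    expect_equal(al$score, align_score_oracle(a, b), info = paste(a, b))
  }
  # single mismatch column, no gaps
  al2 <- pairwise_align("A", "G", gap_open = 0, gap_extend = 2,
                        matrix_name = NULL, match = 1, mismatch = 0)
  expect_equal(al2$a_aligned, "A")
  expect_equal(al2$b_aligned, "G")
})

## ---- progressive alignment -------------------------------------------------

test_that("identical sequences align without gaps", {
  set.seed(602)
  s <- random_protein(60)
  aln <- align_sequences(c(a = s, b = s, c = s))
  expect_false(any(grepl("-", aln)))
  expect_equal(unname(aln), rep(s, 3))
})

test_that("the chromophore Cys column is aligned across receptor groups", {
  gaf_names <- REFS$table$name[REFS$table$kind == "domain" &
                                 REFS$table$label == "GAF"]
  aln <- align_sequences(REFS$seqs[gaf_names])
  cols <- do.call(rbind, strsplit(unname(aln), ""))
  all_c <- which(apply(cols, 2, function(x) all(x == "C")))
  expect_gte(length(all_c), 1L)
})

test_that("two high-identity sequences reduce to the pairwise alignment", {
  set.seed(603)
  a <- random_protein(80)
  b <- mutate_protein(a, 0.1)
  aln <- align_sequences(c(a = a, b = b))
  expect_equal(unname(aln), c(a, b))  # equal length, no indels introduced
})

## ---- JTT distances ---------------------------------------------------------

test_that("JTT distance is zero iff identical, and symmetric", {
  set.seed(604)
  x <- random_protein(120)
  expect_equal(jtt_distance(x, x), 0)
  y <- mutate_protein(x, 0.2)
  expect_gt(jtt_distance(x, y), 0)
  expect_equal(jtt_distance(x, y), jtt_distance(y, x))
  expect_error(jtt_distance(strrep("-", 10), strrep("A", 10)), "shared")
})

test_that("one substitution in 100 columns gives the expected small distance", {
  set.seed(605)
  x <- random_protein(100)
  ch <- strsplit(x, "")[[1]]
  alt <- setdiff(c("A", "R"), ch[[50]])[[1]]
  y <- paste0(substring(x, 1, 49), alt, substring(x, 51))
  d <- jtt_distance(x, y)
  expect_gte(d, 0.005)
  expect_lte(d, 0.03)
  expect_lt(abs(d - jtt_grid_oracle(x, y)), 1e-4)
})

test_that("distance increases with the number of differing columns", {
  set.seed(606)
  x <- random_protein(150)
  ch <- strsplit(x, "")[[1]]
  d_prev <- 0
  for (k in c(3, 10, 25, 45)) {
    y <- ch
    idx <- seq_len(k)
    y[idx] <- vapply(ch[idx], function(a)
      sample(setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I"), a), 1), "")
    d <- jtt_distance(x, paste(y, collapse = ""))
    expect_gt(d, d_prev)
    d_prev <- d
  }
})

test_that("ML distances match the grid-search oracle on random pairs", {
  set.seed(607)
  for (i in 1:10) {
    x <- random_protein(sample(80:200, 1))
    y <- mutate_protein(x, runif(1, 0.02, 0.5))
    d <- jtt_distance(x, y)
    expect_lt(abs(d - jtt_grid_oracle(x, y)), 1e-4, label = paste("pair", i))
  }
})

test_that("the full distance matrix agrees with an independent implementation", {
  set.seed(608)
  seqs <- c(a = random_protein(100))
  seqs["b"] <- mutate_protein(seqs[["a"]], 0.1)
  seqs["c"] <- mutate_protein(seqs[["a"]], 0.3)
  dm <- jtt_dist_matrix(seqs)
  chm <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(chm) <- names(seqs)
  pd <- phangorn::as.phyDat(chm, type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT",
                                     exclude = "pairwise"))
  expect_equal(dm[lower.tri(dm)], ref[rownames(dm), rownames(dm)][lower.tri(dm)],
               tolerance = 1e-3)
})

## ---- neighbor joining ------------------------------------------------------

test_that("NJ recovers the 4-taxon tree and matches the least-squares oracle", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  dm <- ape::cophenetic.phylo(tr)
  est <- nj_tree(dm)
  expect_true(is_split(est, c("A", "B")))
  # branch lengths exactly recovered on an additive matrix
  tip_edges <- est$edge.length[match(seq_along(est$tip.label),
                                     est$edge[, 2])]
  expect_equal(tip_edges[match(c("A", "B", "C", "D"), est$tip.label)],
               c(1, 2, 3, 1))
  oracle <- ls4_oracle(dm)
  expect_equal(oracle$split, c("A", "B"))
  expect_lt(oracle$sse, 1e-12)
})

test_that("an equidistant 3-taxon matrix resolves with equal branches", {
  dm <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(dm) <- 0
  est <- nj_tree(dm)
  expect_equal(sort(est$edge.length), c(1, 1, 1))
})

test_that("identical taxa become siblings", {
  dm <- matrix(c(0, 0, 4, 4,
                 0, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  est <- nj_tree(dm)
  expect_true(is_split(est, c("a", "b")))
})

test_that("NJ recovers the topology of random additive matrices", {
  set.seed(609)
  ok <- 0L
  for (i in 1:30) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
    est <- nj_tree(ape::cophenetic.phylo(tr))
    ok <- ok + (ape::dist.topo(ape::unroot(tr), est) == 0)
  }
  expect_equal(ok, 30L)
})

test_that("NJ needs at least 3 taxa", {
  dm <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(dm), "3 taxa")
})

## ---- bootstrap -------------------------------------------------------------

test_that("bootstrap supports behave at the extremes", {
  set.seed(610)
  a <- random_protein(120)
  grp1 <- c(t1 = a, t2 = mutate_protein(a, 0.03))
  far <- mutate_protein(a, 0.6)
  grp2 <- c(t3 = far, t4 = mutate_protein(far, 0.03))
  aln <- c(grp1, grp2)
  # single replicate: supports are 0 or 100
  tr1 <- bootstrap_tree(aln, n_reps = 1, seed = 1)
  supp <- as.numeric(tr1$node.label[nzchar(tr1$node.label)])
  expect_true(all(supp %in% c(0, 100)))
  # a deep two-group split is supported by every replicate
  tr <- bootstrap_tree(aln, n_reps = 50, seed = 2)
  expect_equal(clade_support(tr, c("t1", "t2")), 100)
})

test_that("bootstrap supports do not depend on taxon input order", {
  set.seed(611)
  seqs <- simulate_gaf_groups(n_per_group = 3, divergence = 0.05, seed = 5)
  tr_a <- bootstrap_tree(seqs, n_reps = 30, seed = 9)
  tr_b <- bootstrap_tree(rev(seqs), n_reps = 30, seed = 9)
  for (grp in c("CcaS", "RcaE", "RfpA")) {
    tips <- grep(grp, names(seqs), value = TRUE)
    expect_equal(clade_support(tr_a, tips), clade_support(tr_b, tips),
                 info = grp)
  }
})

test_that("receptor groups form three clades in simulated GAF trees", {
  seqs <- simulate_gaf_groups(n_per_group = 4, divergence = 0.05, seed = 6)
  aln <- align_sequences(seqs)
  tr <- nj_tree(jtt_dist_matrix(aln))
  for (grp in c("CcaS", "RcaE", "RfpA"))
    expect_true(is_split(tr, grep(grp, names(seqs), value = TRUE)), info = grp)
})
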