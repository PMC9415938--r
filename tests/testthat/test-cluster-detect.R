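# Gene labelling, rfp operon and apc block synteny, FaRLiP assembly and
# locus context.

farlip_units <- function(strand = "+", gap = 100L) {
  genes <- c("rfpB_ref", "rfpA_ref", "rfpC_ref")
  if (strand == "-") genes <- rev(genes)
  lapply(genes, function(n) list(protein = ref_seq(n), strand = strand,
                                 gap = gap, product = n))
}

apc_units <- function(strand = "+", gap = 100L, extra = FALSE) {
  genes <- c("apcD_ref", "apcE_farlip_ref", "apcD_ref", "apcB_ref", "apcD_ref")
  if (extra) genes <- c(genes, "apcD_ref")
  if (strand == "-") genes <- rev(genes)
  lapply(genes, function(n) list(protein = ref_seq(n), strand = strand,
                                 gap = gap, product = n))
}

test_that("genes label after their exemplars, diverged or not", {
  set.seed(401)
  g <- build_genome(list(
    list(protein = ref_seq("pebA_ref")),
    list(protein = mutate_protein(ref_seq("pebB_ref"), 0.10)),
    list(protein = mutate_protein(ref_seq("cpeA_ref"), 0.10)),
    list(protein = random_protein(220))), genome_id = "lb")
  labs <- label_genes(g, REFS)
  expect_equal(labs$label, c("pebA", "pebB", "cpeA", "hypothetical"))
  expect_equal(labs$identity[[1]], 100)
})

test_that("rfp operon is found on either strand and respects the rules", {
  g_plus <- build_genome(farlip_units("+"), genome_id = "opP")
  labs <- label_genes(g_plus, REFS)
  op <- find_rfp_operon(g_plus, labs)
  expect_equal(unname(label_lookup(labs)[as.character(op)]),
               c("rfpB", "rfpA", "rfpC"))

  g_minus <- build_genome(farlip_units("-"), genome_id = "opM")
  labs_m <- label_genes(g_minus, REFS)
  op_m <- find_rfp_operon(g_minus, labs_m)
  expect_false(is.null(op_m))
  expect_equal(unname(label_lookup(labs_m)[as.character(op_m)]),
               c("rfpB", "rfpA", "rfpC"))

  # rfpA without rfpB is not an operon
  g_no_b <- build_genome(list(list(protein = ref_seq("rfpA_ref")),
                              list(protein = ref_seq("rfpC_ref"))),
                         genome_id = "noB")
  expect_null(find_rfp_operon(g_no_b, label_genes(g_no_b, REFS)))

  # an oversized intergenic gap breaks the operon
  wide <- farlip_units("+")
  wide[[2]]$gap <- 400L
  g_wide <- build_genome(wide, genome_id = "wide")
  expect_null(find_rfp_operon(g_wide, label_genes(g_wide, REFS)))

  # mixed strands break the operon
  mixed <- farlip_units("+")
  mixed[[2]]$strand <- "-"
  g_mix <- build_genome(mixed, genome_id = "mix")
  expect_null(find_rfp_operon(g_mix, label_genes(g_mix, REFS)))
})

test_that("apc block matches apcD-E-D-B-D with a tolerated extra apcD", {
  g <- build_genome(apc_units(), genome_id = "ab")
  blk <- find_apc_block(g, label_genes(g, REFS))
  expect_equal(length(blk), 5L)
  expect_false(attr(blk, "extra_apcd"))

  g6 <- build_genome(apc_units(extra = TRUE), genome_id = "ab6")
  blk6 <- find_apc_block(g6, label_genes(g6, REFS))
  expect_equal(length(blk6), 6L)
  expect_true(attr(blk6, "extra_apcd"))

  gm <- build_genome(apc_units("-"), genome_id = "abm")
  expect_false(is.null(find_apc_block(gm, label_genes(gm, REFS))))

  partial <- build_genome(list(
    list(protein = ref_seq("apcD_ref")),
    list(protein = ref_seq("apcE_farlip_ref")),
    list(protein = ref_seq("apcB_ref"))), genome_id = "abp")
  expect_null(find_apc_block(partial, label_genes(partial, REFS)))
})

test_that("FaRLiP requires both parts and records scaffold splits", {
  spec <- synthetic_genome_spec("fl", farlip = TRUE, seed = 11)
  g <- generate_genome(spec)
  labs <- label_genes(g, REFS)
  lks <- classify_linkers(g, REFS)
  fl <- assemble_farlip(g, labs, lks)
  expect_s3_class(fl, "ca_farlip")
  expect_false(fl$scaffold_split)
  expect_gte(length(fl$psi_genes), 2L)
  expect_gte(length(fl$chlf_genes), 1L)

  spec2 <- synthetic_genome_spec("fls", farlip = TRUE, split_farlip = TRUE,
                                 seed = 12)
  g2 <- generate_genome(spec2)
  fl2 <- assemble_farlip(g2, label_genes(g2, REFS), classify_linkers(g2, REFS))
  expect_true(fl2$scaffold_split)
  expect_gte(length(fl2$member_contigs), 2L)

  # apc block alone is not a cluster
  g3 <- build_genome(apc_units(), genome_id = "onlyapc")
  expect_null(assemble_farlip(g3, label_genes(g3, REFS)))
})

test_that("detection is invariant under contig reverse-complementation", {
  spec <- synthetic_genome_spec("rc", farlip = TRUE, seed = 13)
  g <- generate_genome(spec)
  g_rc <- revcomp_contig(g, g$contigs$contig_id[[1]])
  fl <- assemble_farlip(g, label_genes(g, REFS))
  fl_rc <- assemble_farlip(g_rc, label_genes(g_rc, REFS))
  expect_false(is.null(fl_rc))
  expect_setequal(fl_rc$rfp_operon, fl$rfp_operon)
  expect_setequal(fl_rc$apc_block, fl$apc_block)
})

test_that("deleting cluster genes removes the cluster call", {
  spec <- synthetic_genome_spec("ko", farlip = TRUE, seed = 14)
  g <- generate_genome(spec)
  labs <- label_genes(g, REFS)
  rfpb_tag <- labs$locus_tag[labs$label == "rfpB"]
  g_ko <- ca_genome(g$genome_id, g$organism, g$contigs,
                    g$genes[g$genes$locus_tag != rfpb_tag, ])
  expect_null(assemble_farlip(g_ko, label_genes(g_ko, REFS)))
})

test_that("permuting gene order within a contig destroys operon detection", {
  set.seed(402)
  spec <- synthetic_genome_spec("perm", farlip = TRUE, n_decoys = 10L,
                                seed = 15)
  g <- generate_genome(spec)
  labs <- label_genes(g, REFS)
  destroyed <- 0L
  n_trials <- 20L
  for (i in seq_len(n_trials)) {
    perm <- g
    idx <- sample(nrow(g$genes))
    # permute which protein sits at which coordinate slot
    perm$genes$locus_tag <- g$genes$locus_tag[idx]
    perm$genes$protein <- g$genes$protein[idx]
    perm$genes$product <- g$genes$product[idx]
    labs_p <- tibble::tibble(
      locus_tag = perm$genes$locus_tag,
      label = label_lookup(labs)[perm$genes$locus_tag],
      identity = NA_real_)
    if (is.null(find_rfp_operon(perm, labs_p))) destroyed <- destroyed + 1L
  }
  expect_gte(destroyed, n_trials - 1L)
})

test_that("locus context reports neighbours and operon co-members", {
  units <- list(
    list(protein = ref_seq("cpcB_ref"), gap = 300L, strand = "+"),
    list(protein = ref_seq("cpcS_ref"), gap = 300L, strand = "+"),
    list(protein = ref_seq("cpcL_ref"), gap = 80L, strand = "+"),
    list(protein = ref_seq("cpeA_ref"), gap = 151L, strand = "+"),
    list(protein = ref_seq("pebA_ref"), gap = 300L, strand = "+"))
  g <- build_genome(units, genome_id = "ctx")
  labs <- label_genes(g, REFS)
  anchor <- g$genes$locus_tag[[3]]
  ctx <- locus_context(g, anchor, labels = labs)
  # cpcS sits 80 bp upstream on the same strand: co-member
  expect_true(g$genes$locus_tag[[2]] %in% ctx$operon_comembers)
  # the 151 bp gap excludes the downstream gene (threshold boundary)
  expect_false(g$genes$locus_tag[[4]] %in% ctx$operon_comembers)
  expect_equal(ctx$upstream$gene_label, c("cpcB", "cpcS"))
  expect_true(ctx$at_edge)

  lone <- build_genome(list(list(protein = ref_seq("cpcL_ref"))),
                       genome_id = "lone")
  ctx2 <- locus_context(lone, lone$genes$locus_tag[[1]])
  expect_equal(length(ctx2$operon_comembers), 0L)
  expect_true(ctx2$at_edge)
  expect_error(locus_context(lone, "missing"), "anchor")
})
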