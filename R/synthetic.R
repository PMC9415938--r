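# Synthetic annotated genomes with known chromatic-acclimation ground truth.
# The generator embeds diverged copies of the packaged reference exemplars
# into multi-contig genomes, arranges the FaRLiP cluster with operon-scale
# gaps (optionally split across contigs), and pads with decoy open reading
# frames, so every pipeline stage is testable without downloads.

BASELINE_PBS <- c(apcD = 1L, apcB = 1L, apcE = 1L, cpcA = 1L, cpcB = 1L,
                  cpcG = 1L)

implied_ca_truth <- function(photoreceptors, pbs, farlip) {
  cnt <- function(g) if (g %in% names(pbs)) pbs[[g]] else 0L
  pe <- cnt("cpeA") > 0 || cnt("cpeB") > 0
  peb <- cnt("pebA") > 0 && cnt("pebB") > 0
  pec <- cnt("pecA") > 0 || cnt("pecB") > 0
  types <- c(
    if ("CcaS" %in% photoreceptors && cnt("cpcL") >= 1) "CA1",
    if ("CcaS" %in% photoreceptors && pe && peb) "CA2",
    if ("RcaE" %in% photoreceptors && pe && peb) "CA3",
    if (farlip) "CA6",
    if ("CcaS" %in% photoreceptors && pec) "CA7")
  as.character(types)
}

#' Specify a synthetic genome
#'
#' The specification is validated at construction time: the declared
#' `ca_truth` must match what the CA assignment rules imply for the gene
#' content, so fixtures can never disagree with their truth labels.
#'
#' @param genome_id Genome identifier.
#' @param photoreceptors Subset of `c("CcaS", "RcaE", "RfpA")` to embed as
#'   standalone genes. `farlip = TRUE` embeds RfpA inside the rfp operon and
#'   adds it to the photoreceptor truth automatically.
#' @param pbs_genes Named integer vector of per-gene copy numbers; merged
#'   over a baseline of `apcD, apcB, apcE, cpcA, cpcB, cpcG` (one each).
#' @param farlip Embed the full FaRLiP cluster (rfpB-rfpA-rfpC operon,
#'   apcD-E-D-B-D block with a FaRLiP-type apcE, psa/psb/chlF genes).
#' @param split_farlip Place the rfp operon and the apc block on different
#'   contigs.
#' @param extra_apcd Add the tolerated sixth apcD to the apc block.
#' @param divergence Per-site substitution probability applied to embedded
#'   genes (diagnostic columns frozen unless `mutate_diagnostics`).
#' @param n_decoys Number of random decoy ORFs.
#' @param n_gaf_decoys Number of GAF-containing decoy proteins (diverged
#'   receptor GAF domains whose chromophore Cys is substituted).
#' @param n_contigs Number of contigs.
#' @param ca_truth Declared truth (validated); `NULL` to derive it.
#' @param mutate_diagnostics Allow divergence to hit diagnostic columns
#'   (negative-control fixtures only).
#' @param seed Per-genome RNG seed.
#' @return List of class `ca_genome_spec`.
#' @export
synthetic_genome_spec <- function(genome_id,
                                  photoreceptors = character(0),
                                  pbs_genes = integer(0),
                                  farlip = FALSE, split_farlip = FALSE,
                                  extra_apcd = FALSE,
                                  divergence = 0, n_decoys = 5L,
                                  n_gaf_decoys = 2L, n_contigs = 1L,
                                  ca_truth = NULL,
                                  mutate_diagnostics = FALSE, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.3,
            all(photoreceptors %in% c("CcaS", "RcaE", "RfpA")))
  pbs <- BASELINE_PBS
  for (g in names(pbs_genes)) pbs[[g]] <- as.integer(pbs_genes[[g]])
  pr_truth <- union(photoreceptors, if (farlip) "RfpA")
  implied <- implied_ca_truth(pr_truth, pbs, farlip)
  if (is.null(ca_truth)) ca_truth <- implied
  if (!setequal(ca_truth, implied))
    stop("declared ca_truth {", paste(ca_truth, collapse = ","),
         "} contradicts gene content (implies {",
         paste(implied, collapse = ","), "})")
  if (split_farlip && !farlip) stop("split_farlip requires farlip")
  if (split_farlip) n_contigs <- max(n_contigs, 2L)
  structure(list(genome_id = genome_id, photoreceptors = photoreceptors,
                 photoreceptor_truth = sort(pr_truth), pbs_genes = pbs,
                 farlip = farlip, split_farlip = split_farlip,
                 extra_apcd = extra_apcd, divergence = divergence,
                 n_decoys = as.integer(n_decoys),
                 n_gaf_decoys = as.integer(n_gaf_decoys),
                 n_contigs = as.integer(n_contigs),
                 ca_truth = sort(ca_truth),
                 mutate_diagnostics = mutate_diagnostics,
                 seed = as.integer(seed)),
            class = "ca_genome_spec")
}

# exemplar name for an embeddable gene symbol
gene_exemplar <- function(gene) {
  switch(gene,
         CcaS = "ccaS_ref", RcaE = "rcaE_ref", RfpA = "rfpA_ref",
         apcE = "apcE_ref", apcE_farlip = "apcE_farlip_ref",
         paste0(gene, "_ref"))
}

embed_gene <- function(gene, refs, divergence, mutate_diagnostics) {
  ex <- gene_exemplar(gene)
  seq <- refs$seqs[[ex]]
  if (is.null(seq)) stop("no exemplar for gene ", gene)
  frozen <- if (mutate_diagnostics) integer(0) else
    refs$table$frozen[[match(ex, refs$table$name)]]
  mutate_protein(seq, divergence, frozen = frozen)
}

#' Generate a synthetic genome from a specification
#'
#' Embedded genes are reverse-translated, diverged copies of the packaged
#' exemplars; FaRLiP genes are laid out as the rfpB-rfpA-rfpC operon and the
#' apcD-E-D-B-D block with intra-operon gaps of 60-120 bp (on two contigs
#' when `split_farlip`); all other genes are shuffled with 200-400 bp
#' spacers and random strands. Bit-for-bit reproducible given the seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param refs Reference set.
#' @return A [ca_genome()] with the truth labels attached as attributes
#'   `ca_truth` and `photoreceptor_truth`.
#' @export
generate_genome <- function(spec, refs = ca_references()) {
  stopifnot(inherits(spec, "ca_genome_spec"))
  withr::with_seed(spec$seed, generate_genome_impl(spec, refs))
}

generate_genome_impl <- function(spec, refs) {
  div <- spec$divergence
  units <- list()  # each: list(genes = tibble(gene, protein), operon = bool)
  one <- function(gene, product = gene)
    tibble::tibble(gene = gene, product = product,
                   protein = embed_gene(gene, refs, div, spec$mutate_diagnostics))
  # standalone photoreceptors
  for (p in spec$photoreceptors)
    units[[length(units) + 1L]] <- list(genes = one(p), operon = FALSE)
  # pbs genes
  for (g in names(spec$pbs_genes)) for (k in seq_len(spec$pbs_genes[[g]]))
    units[[length(units) + 1L]] <- list(genes = one(g), operon = FALSE)
  # decoys
  for (i in seq_len(spec$n_decoys)) {
    len <- sample(120:450, 1)
    units[[length(units) + 1L]] <- list(
      genes = tibble::tibble(gene = "decoy", product = "hypothetical protein",
                             protein = random_protein(len)),
      operon = FALSE)
  }
  for (i in seq_len(spec$n_gaf_decoys)) {
    grp <- c("CcaS", "RcaE", "RfpA")[(i - 1L) %% 3L + 1L]
    gaf <- mutate_protein(refs$seqs[[sprintf("GAF_%s_1", grp)]], 0.30)
    cys <- diag_col(refs, "GAF", "cys")
    gaf <- paste0(substring(gaf, 1, cys - 1), "S", substring(gaf, cys + 1))
    units[[length(units) + 1L]] <- list(
      genes = tibble::tibble(gene = "gaf_decoy",
                             product = "GAF domain-containing protein",
                             protein = paste0(random_protein(30), gaf,
                                              random_protein(40))),
      operon = FALSE)
  }
  units <- sample(units)  # random gene order
  # FaRLiP operonic blocks (appended after shuffling at random positions)
  rfp_unit <- apc_unit <- NULL
  if (spec$farlip) {
    rfp_unit <- list(genes = dplyr::bind_rows(one("rfpB"), one("RfpA", "rfpA"),
                                              one("rfpC")), operon = TRUE)
    apc_genes <- list(one("apcD"), one("apcE_farlip", "apcE"), one("apcD"),
                      one("apcB"), one("apcD"))
    if (spec$extra_apcd) apc_genes <- c(apc_genes, list(one("apcD")))
    apc_unit <- list(genes = dplyr::bind_rows(apc_genes), operon = TRUE)
    psx <- lapply(c("psaA", "psaB", "psbA", "psbB", "psbC", "psbD", "chlF"), one)
    for (u in psx) units[[length(units) + 1L]] <- list(genes = u, operon = FALSE)
    units <- sample(units)
  }
  # distribute units across contigs
  contig_units <- replicate(spec$n_contigs, list(), simplify = FALSE)
  for (u in units) {
    ci <- sample.int(spec$n_contigs, 1)
    contig_units[[ci]][[length(contig_units[[ci]]) + 1L]] <- u
  }
  if (spec$farlip) {
    if (spec$split_farlip) {
      contig_units[[1]] <- c(contig_units[[1]], list(rfp_unit))
      contig_units[[2]] <- c(contig_units[[2]], list(apc_unit))
    } else {
      ci <- sample.int(spec$n_contigs, 1)
      at <- length(contig_units[[ci]])
      contig_units[[ci]] <- append(contig_units[[ci]],
                                   list(rfp_unit, apc_unit), after = at)
    }
  }
  # lay out sequences
  contigs <- list(); genes <- list(); tag_i <- 0L
  for (ci in seq_len(spec$n_contigs)) {
    parts <- character(0); pos <- 0L
    pad <- chars_seq(random_dna(sample(80:120, 1)))
    parts <- c(parts, pad); pos <- pos + length(pad)
    cid <- sprintf("%s_c%02d", spec$genome_id, ci)
    for (u in contig_units[[ci]]) {
      strand <- sample(c("+", "-"), 1)
      gt <- u$genes
      if (strand == "-") gt <- gt[rev(seq_len(nrow(gt))), ]
      for (gi in seq_len(nrow(gt))) {
        gap_len <- if (u$operon && gi > 1L) sample(60:120, 1)
                   else sample(200:400, 1)
        gap <- chars_seq(random_dna(gap_len))
        parts <- c(parts, gap); pos <- pos + gap_len
        cds <- reverse_translate(gt$protein[[gi]])
        if (strand == "-") cds <- reverse_complement(cds)
        start <- pos + 1L; end <- pos + nchar(cds)
        parts <- c(parts, chars_seq(cds)); pos <- end
        tag_i <- tag_i + 1L
        genes[[length(genes) + 1L]] <- tibble::tibble(
          locus_tag = sprintf("%s_g%03d", spec$genome_id, tag_i),
          contig_id = cid, start = start, end = end, strand = strand,
          product = gt$product[[gi]], protein = gt$protein[[gi]],
          truth_gene = gt$gene[[gi]])
      }
    }
    tail_pad <- chars_seq(random_dna(sample(80:120, 1)))
    parts <- c(parts, tail_pad)
    contigs[[cid]] <- paste(parts, collapse = "")
  }
  genes <- dplyr::bind_rows(genes)
  truth_gene <- stats::setNames(genes$truth_gene, genes$locus_tag)
  genes$truth_gene <- NULL
  g <- ca_genome(spec$genome_id, paste("synthetic cyanobacterium",
                                       spec$genome_id),
                 tibble::tibble(contig_id = names(contigs),
                                sequence = unlist(unname(contigs))),
                 genes)
  attr(g, "ca_truth") <- spec$ca_truth
  attr(g, "photoreceptor_truth") <- spec$photoreceptor_truth
  attr(g, "truth_gene") <- truth_gene
  g
}

#' Archetype specifications spanning every CA rule
#'
#' Ten gene-content archetypes covering CA1 alone (a phycoerythrin-free CA1
#' genome), CA1+CA2, CA2, CA3, CA1+CA2+CA3, CA6, CA3+CA6, CA7 (without PE,
#' as for the known CA7 representative), a non-CA genome (APC/PC only), and
#' an RfpA-like genome with no FaRLiP cluster.
#'
#' @return Named list of argument lists for [synthetic_genome_spec()].
#' @export
ca_archetypes <- function() {
  pe <- c(cpeA = 1L, cpeB = 1L, pebA = 1L, pebB = 1L)
  list(
    ca1_only     = list(photoreceptors = "CcaS", pbs_genes = c(cpcL = 1L)),
    ca1_ca2      = list(photoreceptors = "CcaS", pbs_genes = c(cpcL = 2L, pe)),
    ca2_only     = list(photoreceptors = "CcaS", pbs_genes = pe),
    ca3_only     = list(photoreceptors = "RcaE", pbs_genes = pe),
    ca1_ca2_ca3  = list(photoreceptors = c("CcaS", "RcaE"),
                        pbs_genes = c(cpcL = 2L, pe)),
    ca6_only     = list(farlip = TRUE),
    ca3_ca6      = list(photoreceptors = "RcaE", farlip = TRUE,
                        pbs_genes = c(cpcL = 1L, pe)),
    ca7_only     = list(photoreceptors = "CcaS",
                        pbs_genes = c(pecA = 1L, pecB = 1L)),
    non_ca       = list(),
    rfpa_like    = list(photoreceptors = "RfpA", n_gaf_decoys = 5L))
}

#' Generate a reproducible synthetic cohort
#'
#' @param n Number of genomes; archetypes are cycled.
#' @param divergence Per-site substitution probability for embedded genes.
#' @param seed Master seed; per-genome seeds are derived from it.
#' @param specs Optional list of [synthetic_genome_spec()] argument lists to
#'   cycle instead of [ca_archetypes()].
#' @param out_dir Optional directory: writes per-genome GenBank + protein
#'   FASTA and a `truth.tsv` table.
#' @return List with `genomes` (list of [ca_genome()]) and `truth` (tibble
#'   of `genome_id`, `ca_truth`, `photoreceptors`).
#' @export
generate_cohort <- function(n = 20L, divergence = 0, seed = 1L, specs = NULL,
                            out_dir = NULL) {
  arch <- specs %||% ca_archetypes()
  gseeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  genomes <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    args <- arch[[(i - 1L) %% length(arch) + 1L]]
    args$genome_id <- sprintf("syn%03d", i)
    args$divergence <- divergence
    args$seed <- gseeds[[i]]
    spec <- do.call(synthetic_genome_spec, args)
    g <- generate_genome(spec)
    genomes[[i]] <- g
    truth[[i]] <- tibble::tibble(
      genome_id = spec$genome_id,
      ca_truth = paste(spec$ca_truth, collapse = " "),
      photoreceptors = paste(spec$photoreceptor_truth, collapse = "/"))
  }
  truth <- dplyr::bind_rows(truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in genomes) {
      write_genbank(g, file.path(out_dir, paste0(g$genome_id, ".gbk")))
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(genome_proteins(g)),
        file.path(out_dir, paste0(g$genome_id, ".faa")), width = 70)
    }
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(genomes = genomes, truth = truth)
}

#' Simulate GAF-domain sequences from the three receptor groups
#'
#' Used for the three-group phylogeny property: `n_per_group` diverged
#' copies of each packaged group exemplar.
#'
#' @param n_per_group Sequences per receptor group.
#' @param divergence Per-site substitution probability.
#' @param seed RNG seed.
#' @param refs Reference set.
#' @return Named character vector (`CcaS_1`, ..., `RfpA_n`).
#' @export
simulate_gaf_groups <- function(n_per_group = 10L, divergence = 0.05,
                                seed = 1L, refs = ca_references()) {
  withr::with_seed(seed, {
    out <- character(0)
    for (grp in c("CcaS", "RcaE", "RfpA")) {
      seedseq <- refs$seqs[[sprintf("GAF_%s_1", grp)]]
      frozen <- refs$table$frozen[[match(sprintf("GAF_%s_1", grp),
                                         refs$table$name)]]
      for (i in seq_len(n_per_group))
        out[[sprintf("%s_%d", grp, i)]] <-
          mutate_protein(seedseq, divergence, frozen = frozen)
    }
    out
  })
}
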