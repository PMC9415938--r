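# FaRLiP gene-cluster detection: the rfpB-rfpA-rfpC operon, the
# apcD-E-D-B-D block (with the tolerated extra apcD), photosystem/chlF
# inventory, scaffold-split clusters, and cpcL locus context.

#' Label genes by best reference identity
#'
#' Each protein is labelled after the gene exemplar with the highest global
#' percent identity, provided it reaches the labelling threshold; everything
#' else is `"hypothetical"`. A k-mer containment prescreen avoids aligning
#' against implausible exemplars.
#'
#' @param genome A [ca_genome()].
#' @param refs Reference set.
#' @param opts Options from [ca_options()].
#' @return Tibble: `locus_tag`, `label`, `identity`.
#' @export
label_genes <- function(genome, refs = ca_references(), opts = ca_options()) {
  tbl <- refs$table[refs$table$kind == "gene", ]
  prots <- genome_proteins(genome)
  rows <- lapply(names(prots), function(tag) {
    p <- prots[[tag]]
    row <- memo_call("label", p, opts, label_one_gene(p, tbl, refs, opts))
    row$locus_tag <- tag
    row
  })
  dplyr::bind_rows(rows)
}

label_one_gene <- function(p, tbl, refs, opts) {
  {
    tag <- ""
    pk <- protein_kmers(p, opts$kmer_k)
    cont <- vapply(refs$kmers[tbl$name], function(rk)
      kmer_containment(rk, pk), 1)
    cand <- which(cont >= opts$kmer_min)
    if (!length(cand))
      return(tibble::tibble(locus_tag = tag, label = "hypothetical",
                            identity = NA_real_))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(refs$seqs[tbl$name[cand]])),
      Biostrings::AAString(p), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    pids <- Biostrings::pid(al)
    best <- which.max(pids)
    if (pids[[best]] >= opts$label_identity)
      tibble::tibble(locus_tag = tag, label = tbl$label[cand][[best]],
                     identity = pids[[best]])
    else
      tibble::tibble(locus_tag = tag, label = "hypothetical",
                     identity = pids[[best]])
  }
}

label_lookup <- function(labels) {
  stats::setNames(labels$label, labels$locus_tag)
}

# consecutive-gene windows of a contig's ordered gene table
contig_gene_tables <- function(genome) {
  split(genome$genes, genome$genes$contig_id)
}

#' Find the rfpB-rfpA-rfpC operon
#'
#' Scans every contig for three consecutive, co-stranded genes labelled
#' rfpB, rfpA, rfpC in genomic order (order reversed on the minus strand)
#' with intergenic gaps within the operon limit.
#'
#' @param genome A [ca_genome()].
#' @param labels [label_genes()] output.
#' @param opts Options from [ca_options()].
#' @return Locus tags ordered rfpB, rfpA, rfpC, with the contig in attribute
#'   `contig`; `NULL` when absent. All candidates are kept in attribute
#'   `candidates`; more than one triggers a warning.
#' @export
find_rfp_operon <- function(genome, labels, opts = ca_options()) {
  lab <- label_lookup(labels)
  hits <- list()
  for (gg in contig_gene_tables(genome)) {
    n <- nrow(gg)
    if (n < 3) next
    gl <- lab[gg$locus_tag]
    for (i in seq_len(n - 2L)) {
      trio <- gg[i:(i + 2L), ]
      if (length(unique(trio$strand)) != 1) next
      gaps <- trio$start[-1] - trio$end[-3] - 1L
      if (any(gaps > opts$operon_gap)) next
      lt <- gl[i:(i + 2L)]
      if (trio$strand[[1]] == "+" && identical(unname(lt), c("rfpB", "rfpA", "rfpC")))
        hits[[length(hits) + 1L]] <- structure(trio$locus_tag,
                                               contig = trio$contig_id[[1]])
      if (trio$strand[[1]] == "-" && identical(unname(lt), c("rfpC", "rfpA", "rfpB")))
        hits[[length(hits) + 1L]] <- structure(rev(trio$locus_tag),
                                               contig = trio$contig_id[[1]])
    }
  }
  if (!length(hits)) return(NULL)
  if (length(hits) > 1)
    warning("multiple rfpB-rfpA-rfpC operon candidates; reporting the first")
  structure(hits[[1]], candidates = hits)
}

#' Find the apcD-E-D-B-D block of the FaRLiP cluster
#'
#' Looks for five consecutive genes labelled apcD, apcE, apcD, apcB, apcD
#' (read in either genomic orientation); a single additional apcD inside the
#' window is tolerated and flagged.
#'
#' @inheritParams find_rfp_operon
#' @return Locus tags in apcD-E-D-B-D order (extra apcD retained in place)
#'   with attributes `contig` and `extra_apcd`; `NULL` when absent.
#' @export
find_apc_block <- function(genome, labels, opts = ca_options()) {
  lab <- label_lookup(labels)
  pattern <- c("apcD", "apcE", "apcD", "apcB", "apcD")
  matches_pattern <- function(x) {
    if (identical(x, pattern)) return("exact")
    if (length(x) == 6 && sum(x == "apcD") == 4) {
      for (drop in which(x == "apcD"))
        if (identical(x[-drop], pattern)) return("extra")
    }
    "no"
  }
  for (gg in contig_gene_tables(genome)) {
    n <- nrow(gg)
    gl <- unname(lab[gg$locus_tag])
    for (w in c(6L, 5L)) {  # prefer the extra-apcD window so it is flagged
      if (n < w) next
      for (i in seq_len(n - w + 1L)) {
        win <- gl[i:(i + w - 1L)]
        for (orient in list(identity, rev)) {
          m <- matches_pattern(orient(win))
          if (m != "no") {
            tags <- orient(gg$locus_tag[i:(i + w - 1L)])
            return(structure(tags, contig = gg$contig_id[[i]],
                             extra_apcd = (m == "extra")))
          }
        }
      }
    }
  }
  NULL
}

#' Assemble the FaRLiP cluster call for a genome
#'
#' A FaRLiP cluster is reported iff both the rfpB-rfpA-rfpC operon and the
#' apcD-E-D-B-D block are present; they may sit on different contigs
#' (scaffold-split clusters). Photosystem (psa/psb) and chlF gene content is
#' attached as evidence, and anomalies (missing photosystem genes, an apc
#' block whose apcE does not classify as the FaRLiP form) are recorded as
#' notes, not failures.
#'
#' @param genome A [ca_genome()].
#' @param labels [label_genes()] output.
#' @param linker_calls Optional [classify_linkers()] output, used to check
#'   the apc-block apcE.
#' @param opts Options from [ca_options()].
#' @return A list of class `ca_farlip` (fields `genome_id`, `rfp_operon`,
#'   `apc_block`, `psi_genes`, `psii_genes`, `chlf_genes`, `scaffold_split`,
#'   `member_contigs`, `extra_apcd`, `notes`), or `NULL`.
#' @export
assemble_farlip <- function(genome, labels, linker_calls = NULL,
                            opts = ca_options()) {
  rfp <- find_rfp_operon(genome, labels, opts)
  apc <- find_apc_block(genome, labels, opts)
  if (is.null(rfp) || is.null(apc)) return(NULL)
  lab <- label_lookup(labels)
  notes <- character(0)
  psi <- names(lab)[lab %in% c("psaA", "psaB")]
  psii <- names(lab)[lab %in% c("psbA", "psbB", "psbC", "psbD")]
  chlf <- names(lab)[lab == "chlF"]
  for (need in c("psaA", "psaB")) if (!any(lab == need))
    notes <- c(notes, paste0("no ", need, " detected"))
  if (!length(chlf)) notes <- c(notes, "no chlF detected")
  if (!is.null(linker_calls)) {
    apce_tag <- as.character(apc)[lab[as.character(apc)] == "apcE"][1]
    lc <- linker_calls[linker_calls$locus_tag == apce_tag, ]
    if (nrow(lc) == 1 && lc$klass != "ApcE-FaRLiP")
      notes <- c(notes, sprintf("apc-block apcE %s classifies %s, not ApcE-FaRLiP",
                                apce_tag, lc$klass))
  }
  contigs <- unique(c(attr(rfp, "contig"), attr(apc, "contig")))
  structure(list(
    genome_id = genome$genome_id,
    rfp_operon = as.character(rfp),
    apc_block = as.character(apc),
    psi_genes = psi, psii_genes = psii, chlf_genes = chlf,
    scaffold_split = length(contigs) > 1L,
    member_contigs = contigs,
    extra_apcd = isTRUE(attr(apc, "extra_apcd")),
    notes = notes), class = "ca_farlip")
}

#' @export
print.ca_farlip <- function(x, ...) {
  cat("<ca_farlip> genome", x$genome_id,
      if (x$scaffold_split) "(scaffold-split)" else "", "\n")
  cat("  rfp operon:", paste(x$rfp_operon, collapse = "-"), "\n")
  cat("  apc block: ", paste(x$apc_block, collapse = "-"), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Locus context around an anchor gene
#'
#' Returns the `k` nearest genes on each side of the anchor and the maximal
#' run of co-stranded neighbours with intergenic gaps within the operon
#' limit (putative operon co-members).
#'
#' @param genome A [ca_genome()].
#' @param anchor Locus tag of the anchor gene.
#' @param labels Optional [label_genes()] output used to annotate neighbours.
#' @param k Number of flanking genes per side.
#' @param gap_max Maximum intergenic gap (bp) within an operon run.
#' @return List of class `ca_locus_context`: `anchor`, `upstream`,
#'   `downstream` (tibbles of `locus_tag`, `gene_label`), `operon_comembers`,
#'   `at_edge`, `k`, `gap_max`.
#' @export
locus_context <- function(genome, anchor, labels = NULL, k = 5L,
                          gap_max = 150L) {
  gi <- which(genome$genes$locus_tag == anchor)
  if (!length(gi)) stop("anchor not found: ", anchor)
  cid <- genome$genes$contig_id[[gi]]
  gg <- genome$genes[genome$genes$contig_id == cid, ]
  i <- which(gg$locus_tag == anchor)
  lab <- if (is.null(labels)) {
    stats::setNames(gg$product, gg$locus_tag)
  } else label_lookup(labels)
  up_idx <- if (i == 1L) integer(0) else seq(max(1L, i - k), i - 1L)
  dn_idx <- if (i == nrow(gg)) integer(0) else seq(i + 1L, min(nrow(gg), i + k))
  ctx <- function(idx) tibble::tibble(
    locus_tag = gg$locus_tag[idx],
    gene_label = unname(lab[gg$locus_tag[idx]]))
  # maximal co-stranded, gap-bounded run through the anchor
  co <- i
  j <- i
  while (j > 1L && gg$strand[[j - 1L]] == gg$strand[[i]] &&
         gg$start[[j]] - gg$end[[j - 1L]] - 1L <= gap_max) {
    j <- j - 1L; co <- c(j, co)
  }
  j <- i
  while (j < nrow(gg) && gg$strand[[j + 1L]] == gg$strand[[i]] &&
         gg$start[[j + 1L]] - gg$end[[j]] - 1L <= gap_max) {
    j <- j + 1L; co <- c(co, j)
  }
  structure(list(
    anchor = anchor,
    upstream = ctx(up_idx),
    downstream = ctx(dn_idx),
    operon_comembers = setdiff(gg$locus_tag[co], anchor),
    at_edge = (i - k < 1L) || (i + k > nrow(gg)),
    k = k, gap_max = gap_max), class = "ca_locus_context")
}
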