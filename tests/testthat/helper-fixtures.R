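# Shared fixtures: reference set handle and small genome builders.

REFS <- ca_references()

ref_seq <- function(name) REFS$seqs[[name]]

# moderately hydrophilic stretch (serine/threonine/glycine rich)
hydrophilic_tail <- function(n) {
  paste(rep(c("S", "T", "G", "N", "Q"), length.out = n), collapse = "")
}

# charged hydrophilic stretch
charged_tail <- function(n) {
  paste(rep(c("D", "E", "K", "R", "N"), length.out = n), collapse = "")
}

# Build a single-contig genome from an ordered list of gene units:
# list(protein =, strand = "+", gap = 300, product = "x")
build_genome <- function(units, genome_id = "fix", pad = 100L) {
  genes <- list()
  seqparts <- list(paste(rep("A", pad), collapse = ""))
  pos <- pad
  for (i in seq_along(units)) {
    u <- units[[i]]
    gap <- u$gap %||% 300L
    strand <- u$strand %||% "+"
    gapseq <- paste(rep(c("A", "C", "G", "T"), length.out = gap), collapse = "")
    cds <- catyper::reverse_translate(u$protein)
    if (strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    seqparts <- c(seqparts, gapseq, cds)
    start <- pos + gap + 1L
    end <- start + nchar(cds) - 1L
    pos <- end
    genes[[i]] <- tibble::tibble(
      locus_tag = sprintf("%s_g%02d", genome_id, i),
      contig_id = paste0(genome_id, "_c1"),
      start = start, end = end, strand = strand,
      product = u$product %||% "hypothetical protein",
      protein = u$protein)
  }
  seqparts <- c(seqparts, paste(rep("T", pad), collapse = ""))
  ca_genome(genome_id, paste("fixture", genome_id),
            tibble::tibble(contig_id = paste0(genome_id, "_c1"),
                           sequence = paste(unlist(seqparts), collapse = "")),
            dplyr::bind_rows(genes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse-complement an entire contig of a genome, recomputing gene
# coordinates and strands (for strand/reorder invariance checks)
revcomp_contig <- function(genome, contig_id) {
  ci <- match(contig_id, genome$contigs$contig_id)
  seq <- genome$contigs$sequence[[ci]]
  L <- nchar(seq)
  genome$contigs$sequence[[ci]] <-
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  sel <- genome$genes$contig_id == contig_id
  old_start <- genome$genes$start[sel]
  old_end <- genome$genes$end[sel]
  genome$genes$start[sel] <- L - old_end + 1L
  genome$genes$end[sel] <- L - old_start + 1L
  genome$genes$strand[sel] <- ifelse(genome$genes$strand[sel] == "+", "-", "+")
  ca_genome(genome$genome_id, genome$organism, genome$contigs, genome$genes)
}
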