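# Genome intake: a uniform in-memory data model (ca_genome) fed by GenBank
# flat files or GFF3 + genomic FASTA, plus protein-FASTA ingest.

#' Construct an annotated genome object
#'
#' The container every downstream stage consumes: contigs plus a strand-aware,
#' coordinate-bearing gene table. Coordinates are 1-based inclusive (GenBank
#' convention) throughout the package.
#'
#' @param genome_id Genome identifier.
#' @param organism Organism name.
#' @param contigs Tibble with columns `contig_id`, `sequence`.
#' @param genes Tibble with columns `locus_tag`, `contig_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `product`, `protein`.
#' @return An object of class `ca_genome`.
#' @export
ca_genome <- function(genome_id, organism, contigs, genes) {
  contigs <- tibble::as_tibble(contigs)
  genes <- tibble::as_tibble(genes)
  genes <- dplyr::arrange(genes, .data$contig_id, .data$start)
  g <- structure(list(genome_id = genome_id, organism = organism,
                      contigs = contigs, genes = genes),
                 class = "ca_genome")
  validate_ca_genome(g)
  g
}

validate_ca_genome <- function(g) {
  stopifnot(is.character(g$genome_id), length(g$genome_id) == 1)
  if (anyDuplicated(g$contigs$contig_id))
    stop("duplicate contig_id in genome ", g$genome_id)
  if (anyDuplicated(g$genes$locus_tag))
    stop("duplicate locus_tag in genome ", g$genome_id)
  bad <- setdiff(g$genes$contig_id, g$contigs$contig_id)
  if (length(bad))
    stop("gene contig_id not in contigs: ", paste(bad, collapse = ", "))
  clen <- stats::setNames(nchar(g$contigs$sequence), g$contigs$contig_id)
  with(g$genes, {
    if (any(start < 1 | end > clen[contig_id]))
      stop("gene coordinates outside contig bounds")
    if (any(end < start)) stop("gene end < start")
    if (any(end - start + 1 < 3)) stop("gene shorter than one codon")
    if (any(!nzchar(protein)))
      stop("coding feature without protein sequence: ",
           paste(locus_tag[!nzchar(protein)], collapse = ", "))
  })
  invisible(g)
}

#' @export
print.ca_genome <- function(x, ...) {
  cat("<ca_genome> ", x$genome_id, " (", x$organism, ")\n", sep = "")
  cat("  contigs: ", nrow(x$contigs), " (",
      sum(nchar(x$contigs$sequence)), " bp)\n", sep = "")
  cat("  genes:   ", nrow(x$genes), "\n", sep = "")
  invisible(x)
}

#' Extract the protein set of a genome
#'
#' @param genome A `ca_genome`.
#' @return Named character vector, locus tag to amino-acid sequence.
#' @export
genome_proteins <- function(genome) {
  stats::setNames(genome$genes$protein, genome$genes$locus_tag)
}

# --- GenBank flat file ------------------------------------------------------

#' Read an annotated genome
#'
#' @param path GenBank flat file, or a GFF3 file when `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta Genomic FASTA path (required for GFF3 input).
#' @param genome_id,organism Override identifiers parsed from the file.
#' @return A [ca_genome()] with genes sorted by contig and start coordinate.
#' @export
read_genome <- function(path, format = c("genbank", "gff3"), fasta = NULL,
                        genome_id = NULL, organism = NULL) {
  format <- match.arg(format)
  g <- switch(format,
              genbank = read_genbank(path),
              gff3 = read_gff3_genome(path, fasta))
  if (!is.null(genome_id)) g$genome_id <- genome_id
  if (!is.null(organism)) g$organism <- organism
  validate_ca_genome(g)
  g
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(startsWith(lines, "LOCUS")))
  recs <- recs[vapply(recs, function(r) any(startsWith(r, "LOCUS")), TRUE)]
  if (!length(recs))
    stop("not a GenBank flat file (no LOCUS record): ", path)
  contigs <- list(); genes <- list()
  genome_id <- NA_character_; organism <- NA_character_
  for (rec in recs) {
    loc <- strsplit(trimws(rec[[1]]), "\\s+")[[1]]
    if (length(loc) < 3 || is.na(suppressWarnings(as.integer(loc[[3]]))))
      stop("malformed LOCUS line: ", rec[[1]])
    contig_id <- loc[[2]]
    def <- grep("^DEFINITION", rec, value = TRUE)
    if (length(def)) {
      m <- regmatches(def[[1]], regexec("\\[genome_id=([^]]+)\\]", def[[1]]))[[1]]
      if (length(m) == 2) genome_id <- m[[2]]
      organism <- trimws(sub("DEFINITION\\s+", "", sub("\\[genome_id=.*", "", def[[1]])))
    }
    ori <- which(startsWith(rec, "ORIGIN"))
    end <- which(startsWith(rec, "//"))
    if (!length(ori) || !length(end))
      stop("GenBank record ", contig_id, " missing ORIGIN/terminator")
    seqlines <- rec[(ori + 1):(end - 1)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
    contigs[[contig_id]] <- sequence
    genes[[contig_id]] <- parse_genbank_features(rec[seq_len(ori - 1)],
                                                 contig_id, sequence)
  }
  contigs <- tibble::tibble(contig_id = names(contigs),
                            sequence = unlist(unname(contigs)))
  genes <- dplyr::bind_rows(genes)
  if (is.na(genome_id)) genome_id <- contigs$contig_id[[1]]
  if (is.na(organism)) organism <- genome_id
  ca_genome(genome_id, organism, contigs, genes)
}

parse_genbank_features <- function(rec, contig_id, sequence) {
  fstart <- which(startsWith(rec, "FEATURES"))
  if (!length(fstart)) return(NULL)
  body <- rec[(fstart + 1):length(rec)]
  # feature boundaries: key lines start at column 6
  is_key <- grepl("^ {5}\\S", body)
  idx <- cumsum(is_key)
  out <- list()
  for (blk in split(body, idx)) {
    key <- strsplit(trimws(blk[[1]]), "\\s+")[[1]]
    if (key[[1]] != "CDS") next
    rest <- trimws(blk[-1])
    qs <- which(startsWith(rest, "/"))
    nloc <- if (length(qs)) qs[[1]] - 1L else length(rest)
    locstr <- gsub("\\s", "",
                   paste0(key[[2]], paste(rest[seq_len(nloc)], collapse = "")))
    strand <- if (grepl("complement", locstr)) "-" else "+"
    coords <- as.integer(unlist(regmatches(locstr, gregexpr("[0-9]+", locstr))))
    if (length(coords) < 2) stop("unparseable CDS location: ", locstr)
    start <- min(coords); end <- max(coords)
    quals <- parse_genbank_qualifiers(blk[-1])
    tag <- quals[["locus_tag"]] %||% paste0(contig_id, "_", start)
    prot <- quals[["translation"]]
    if (is.null(prot)) {
      nt <- substring(sequence, start, end)
      if (strand == "-") nt <- reverse_complement(nt)
      prot <- tryCatch(translate_cds(nt), error = function(e) NULL)
      if (is.null(prot) || !nzchar(prot) || grepl("\\*", prot))
        stop("CDS without usable translation: locus_tag ", tag)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      locus_tag = tag, contig_id = contig_id, start = start, end = end,
      strand = strand, product = quals[["product"]] %||% "hypothetical protein",
      protein = gsub("\\*$", "", toupper(prot)))
  }
  dplyr::bind_rows(out)
}

parse_genbank_qualifiers <- function(lines) {
  lines <- trimws(lines)
  starts <- grepl("^/", lines)
  if (!any(starts)) return(list())
  grp <- cumsum(starts)
  quals <- list()
  for (q in split(lines[grp > 0], grp[grp > 0])) {
    txt <- paste(q, collapse = "")
    m <- regmatches(txt, regexec('^/([^=]+)=?"?([^"]*)"?', txt))[[1]]
    if (length(m) == 3) quals[[m[[2]]]] <- m[[3]]
  }
  quals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genome as a GenBank flat file
#'
#' One record per contig; CDS features carry locus_tag, product and
#' translation qualifiers.
#'
#' @param genome A `ca_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genome$contigs))) {
    cid <- genome$contigs$contig_id[[i]]
    seq <- genome$contigs$sequence[[i]]
    writeLines(sprintf("LOCUS       %-17s %d bp    DNA     linear   BCT 01-JAN-2024",
                       cid, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s [genome_id=%s]", genome$organism,
                       genome$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    writeLines(sprintf('                     /organism="%s"', genome$organism), con)
    gg <- genome$genes[genome$genes$contig_id == cid, ]
    for (j in seq_len(nrow(gg))) {
      loc <- sprintf("%d..%d", gg$start[[j]], gg$end[[j]])
      if (gg$strand[[j]] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', gg$locus_tag[[j]]), con)
      writeLines(sprintf('                     /product="%s"', gg$product[[j]]), con)
      tr <- gg$protein[[j]]
      chunks <- substring(tr, seq(1, nchar(tr), 44), pmin(seq(44, nchar(tr) + 43, 44), nchar(tr)))
      writeLines(sprintf('                     /translation="%s"',
                         paste(chunks, collapse = "\n                     ")), con)
    }
    writeLines("ORIGIN", con)
    for (p in seq(1, nchar(seq), 60)) {
      chunk <- substring(seq, p, min(p + 59, nchar(seq)))
      s10 <- seq(1, nchar(chunk), 10)
      block <- substring(chunk, s10, pmin(s10 + 9, nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(block, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# --- GFF3 + FASTA -----------------------------------------------------------

read_gff3_genome <- function(path, fasta) {
  if (is.null(fasta)) stop("GFF3 input requires the genomic FASTA via `fasta=`")
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  dna <- Biostrings::readDNAStringSet(fasta)
  names(dna) <- sub("\\s.*", "", names(dna))
  contigs <- tibble::tibble(contig_id = names(dna),
                            sequence = as.character(dna))
  tags <- gr$locus_tag %||% gr$ID
  if (is.null(tags)) tags <- paste0("gene", seq_along(gr))
  genes <- tibble::tibble(
    locus_tag = as.character(tags),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if (!is.null(gr$product)) as.character(gr$product) else "hypothetical protein"
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genes$protein <- vapply(seq_len(nrow(genes)), function(i) {
    nt <- substring(contigs$sequence[match(genes$contig_id[[i]], contigs$contig_id)],
                    genes$start[[i]], genes$end[[i]])
    if (genes$strand[[i]] == "-") nt <- reverse_complement(nt)
    translate_cds(nt)
  }, "")
  ca_genome(genome_id = sub("\\.gff3?$", "", basename(path)),
            organism = sub("\\.gff3?$", "", basename(path)), contigs, genes)
}

#' Write a genome as canonical GFF3 + FASTA
#'
#' Emits `<id>.gff3`, `<id>.fna` (genomic) and `<id>.faa` (proteins keyed by
#' locus tag) into `dir`.
#'
#' @param genome A `ca_genome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, genome$genome_id)
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genes$contig_id,
    ranges = IRanges::IRanges(genome$genes$start, genome$genes$end),
    strand = genome$genes$strand)
  gr$type <- "CDS"
  gr$source <- "catyper"
  gr$phase <- 0L
  gr$locus_tag <- genome$genes$locus_tag
  gr$ID <- genome$genes$locus_tag
  gr$product <- genome$genes$product
  rtracklayer::export(gr, paste0(base, ".gff3"), format = "gff3")
  dna <- Biostrings::DNAStringSet(stats::setNames(genome$contigs$sequence,
                                                  genome$contigs$contig_id))
  Biostrings::writeXStringSet(dna, paste0(base, ".fna"), width = 70)
  aa <- Biostrings::AAStringSet(genome_proteins(genome))
  Biostrings::writeXStringSet(aa, paste0(base, ".faa"), width = 70)
  invisible(c(gff3 = paste0(base, ".gff3"), fna = paste0(base, ".fna"),
              faa = paste0(base, ".faa")))
}

#' Read a protein FASTA keyed by locus tag
#'
#' @param path Amino-acid FASTA file.
#' @param tag_regex Regular expression whose first capture group extracts the
#'   locus tag from each header; the default takes the first
#'   whitespace-delimited token.
#' @return Tibble with columns `locus_tag`, `protein`.
#' @export
read_proteins <- function(path, tag_regex = "^(\\S+)") {
  if (file.size(path) == 0) {
    warning("empty protein FASTA: ", path)
    return(tibble::tibble(locus_tag = character(0), protein = character(0)))
  }
  aa <- Biostrings::readAAStringSet(path)
  tags <- vapply(names(aa), function(h) {
    m <- regmatches(h, regexec(tag_regex, h))[[1]]
    if (length(m) >= 2) m[[2]] else h
  }, "", USE.NAMES = FALSE)
  if (anyDuplicated(tags))
    stop("duplicate locus tags in ", path, ": ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "))
  seqs <- toupper(sub("\\*+$", "", as.character(aa)))
  ntish <- vapply(seqs, function(s) {
    mean(seq_chars(s) %in% c("A", "C", "G", "T", "N")) >= 0.95
  }, TRUE, USE.NAMES = FALSE)
  if (any(ntish))
    warning("records look nucleotide (>=95% ACGTN): ",
            paste(tags[ntish], collapse = ", "))
  tibble::tibble(locus_tag = tags, protein = unname(seqs))
}
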