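# Domain architecture scanning and photoreceptor classification. Pairwise
# local alignment against packaged exemplars replaces remote homology
# searches; a k-mer containment prescreen keeps cohort-scale scans cheap.

align_local <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
}

align_global <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
}

# Does the protein pass the k-mer prescreen for any exemplar in `names`?
prescreen_any <- function(protein_kmer_set, refs, names, opts) {
  any(vapply(refs$kmers[names], function(rk)
    kmer_containment(rk, protein_kmer_set) >= opts$kmer_min, TRUE))
}

#' Locate reference domains on a protein
#'
#' Each domain kind is searched by iterated local alignment of its packaged
#' exemplars: the best-scoring hit above the identity threshold is recorded,
#' its span masked, and the search repeated, so tandem repeats (e.g. the
#' linker repeats of ApcE) yield one non-overlapping hit each.
#'
#' @param protein Amino-acid string.
#' @param refs Reference set from [ca_references()].
#' @param kinds Domain kinds to search (default: all packaged kinds).
#' @param opts Options from [ca_options()].
#' @param prescreen Apply the k-mer containment prescreen before aligning.
#' @return Tibble of hits: `domain_kind`, `start`, `end`, `score` (percent
#'   identity over the aligned span), `best_reference`; zero rows when
#'   nothing passes the threshold.
#' @export
find_domains <- function(protein, refs = ca_references(),
                         kinds = c("GAF", "PAS", "HisKinase", "PBS-linker",
                                   "phycobiliprotein"),
                         opts = ca_options(), prescreen = TRUE) {
  out <- list()
  pids_first <- list()
  pk <- if (prescreen) protein_kmers(protein, opts$kmer_k) else NULL
  for (kind in kinds) {
    ex_names <- ref_names(refs, kind = kind)
    if (!length(ex_names)) next
    ex_lens <- nchar(refs$seqs[ex_names])
    if (nchar(protein) < min(ex_lens) * opts$span_window[[1]]) next
    if (prescreen && !prescreen_any(pk, refs, ex_names, opts)) next
    masked <- protein
    cap <- if (kind %in% names(opts$max_hits)) opts$max_hits[[kind]] else 8L
    for (rep in seq_len(cap)) {
      al <- align_local(unname(refs$seqs[ex_names]), masked)
      pids <- Biostrings::pid(al)
      if (rep == 1L) pids_first[[kind]] <- stats::setNames(pids, ex_names)
      sc <- Biostrings::score(al)
      ord <- order(sc, decreasing = TRUE)
      best <- NULL
      for (i in ord) {
        s <- Biostrings::start(Biostrings::subject(al))[[i]]
        e <- Biostrings::end(Biostrings::subject(al))[[i]]
        span <- e - s + 1L
        ok_len <- span >= ex_lens[[i]] * opts$span_window[[1]] &&
          span <= ex_lens[[i]] * opts$span_window[[2]]
        if (pids[[i]] >= opts$detect_identity && ok_len) {
          best <- list(i = i, s = s, e = e, pid = pids[[i]]); break
        }
      }
      if (is.null(best)) break
      out[[length(out) + 1L]] <- tibble::tibble(
        domain_kind = kind, start = best$s, end = best$e,
        score = best$pid, best_reference = ex_names[[best$i]])
      masked <- paste0(substring(masked, 1, best$s - 1L),
                       strrep("X", best$e - best$s + 1L),
                       substring(masked, best$e + 1L))
    }
  }
  res <- if (!length(out)) {
    tibble::tibble(domain_kind = character(0), start = integer(0),
                   end = integer(0), score = numeric(0),
                   best_reference = character(0))
  } else dplyr::arrange(dplyr::bind_rows(out), .data$start)
  attr(res, "exemplar_pids") <- pids_first
  res
}

# Map reference columns to query positions from a global alignment
# (pattern = query span, subject = reference exemplar).
alignment_map <- function(aln) {
  p <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  qpos <- cumsum(p != "-")
  rcol <- cumsum(s != "-")
  keep <- s != "-"
  tibble::tibble(ref_col = rcol[keep],
                 query_pos = ifelse(p[keep] == "-", NA_integer_, qpos[keep]),
                 query_res = ifelse(p[keep] == "-", NA_character_, p[keep]))
}

#' Read the diagnostic-residue state of a GAF hit
#'
#' Globally aligns the hit span to its best reference exemplar and reports
#' the chromophore-binding cysteine position (absent when the reference Cys
#' column aligns to a gap or a non-Cys residue), the residue adjacent to it,
#' and the protochromic-triad residues.
#'
#' @param protein Amino-acid string carrying the hit.
#' @param gaf_hit One row of [find_domains()] output with
#'   `domain_kind == "GAF"`.
#' @param refs Reference set.
#' @return List of class `ca_motif`: `cys_pos` (protein coordinate or `NA`),
#'   `adj_residue`, `triad` (three residues), `map` (reference column to
#'   query position), `notes`.
#' @export
extract_motif_state <- function(protein, gaf_hit, refs = ca_references()) {
  stopifnot(gaf_hit$domain_kind == "GAF")
  span <- substring(protein, gaf_hit$start, gaf_hit$end)
  refseq <- refs$seqs[[gaf_hit$best_reference]]
  map <- alignment_map(align_global(span, refseq))
  notes <- character(0)
  get_at <- function(col) map[map$ref_col == col, ]
  cys_col <- diag_col(refs, "GAF", "cys")
  cc <- get_at(cys_col)
  if (nrow(cc) == 0) {
    cys_pos <- NA_integer_; adj <- NA_character_
    notes <- c(notes, "alignment does not cover the reference Cys column")
  } else if (is.na(cc$query_pos) || cc$query_res != "C") {
    cys_pos <- NA_integer_; adj <- NA_character_
    if (!is.na(cc$query_res))
      notes <- c(notes, paste0("reference Cys column occupied by ", cc$query_res))
    else notes <- c(notes, "reference Cys column aligns to a gap")
  } else {
    cys_pos <- gaf_hit$start - 1L + cc$query_pos
    adj <- substring(protein, cys_pos + 1L, cys_pos + 1L)
  }
  triad_cols <- vapply(paste0("triad", 1:3), function(f) diag_col(refs, "GAF", f), 1)
  triad <- vapply(triad_cols, function(col) {
    r <- get_at(col)
    if (nrow(r) == 0 || is.na(r$query_res)) NA_character_ else r$query_res
  }, "")
  structure(list(cys_pos = cys_pos, adj_residue = adj, triad = unname(triad),
                 map = map, notes = notes), class = "ca_motif")
}

# best local GAF identity of the protein against each receptor group
gaf_group_identity <- function(protein, refs = ca_references()) {
  tbl <- refs$table[refs$table$kind == "domain" & refs$table$label == "GAF", ]
  al <- align_local(unname(refs$seqs[tbl$name]), protein)
  pids <- Biostrings::pid(al)
  vapply(split(pids, tbl$group), max, 1)
}

#' Classify a GAF-containing protein as CcaS, RcaE, RfpA or GAF-other
#'
#' Group assignment is by highest local GAF identity among the three receptor
#' groups, demoted to `GAF-other` when the identity falls below the
#' assignment threshold, when the group's required domain architecture is
#' missing (PAS+GAF+histidine kinase for RfpA; GAF+histidine kinase for CcaS
#' and RcaE), or when the chromophore-binding Cys is absent. The His/Leu
#' residue next to the Cys is recorded as evidence and used only to break
#' identity ties.
#'
#' @param locus_tag Identifier for the protein.
#' @param protein Amino-acid string.
#' @param hits [find_domains()] output for this protein (must contain a GAF
#'   hit).
#' @param motif Optional precomputed [extract_motif_state()] result.
#' @param refs Reference set.
#' @param opts Options from [ca_options()].
#' @param group_identity Optional precomputed per-group GAF identities
#'   (named numeric over CcaS/RcaE/RfpA); computed when `NULL`.
#' @return One-row tibble: `locus_tag`, `klass`, `architecture`,
#'   `gaf_identity`, `cys_pos`, `adj_residue`, `triad`, `evidence`.
#' @export
classify_photoreceptor <- function(locus_tag, protein, hits, motif = NULL,
                                   refs = ca_references(), opts = ca_options(),
                                   group_identity = NULL) {
  gaf <- hits[hits$domain_kind == "GAF", ]
  if (nrow(gaf) == 0) stop("classify_photoreceptor requires a GAF hit")
  gaf <- gaf[which.max(gaf$score), ]
  if (is.null(motif)) motif <- extract_motif_state(protein, gaf, refs)
  ident <- group_identity %||% gaf_group_identity(protein, refs)
  arch <- unique(hits$domain_kind[order(hits$start)])
  notes <- character(0)

  top <- max(ident)
  tied <- names(ident)[ident >= top - 1e-9]
  klass <- tied[[1]]
  if (length(tied) > 1) {
    by_motif <- if (identical(motif$adj_residue, "H")) intersect(tied, "RfpA")
                else if (identical(motif$adj_residue, "L")) intersect(tied, c("CcaS", "RcaE"))
                else character(0)
    if (length(by_motif) == 1) {
      klass <- by_motif
      notes <- c(notes, "identity tie broken by Cys-adjacent motif")
    } else if ("RfpA" %in% tied && "PAS" %in% arch && length(by_motif) == 0) {
      klass <- "RfpA"
      notes <- c(notes, "identity tie broken by PAS architecture")
    } else {
      notes <- c(notes, paste0("ambiguous identity tie: ",
                               paste(tied, collapse = "/")))
    }
  }

  required <- if (klass == "RfpA") c("PAS", "GAF", "HisKinase")
              else c("GAF", "HisKinase")
  demote <- FALSE
  if (ident[[klass]] < opts$assign_identity) {
    demote <- TRUE
    notes <- c(notes, sprintf("GAF identity %.1f below assignment threshold",
                              ident[[klass]]))
  }
  if (!all(required %in% arch)) {
    demote <- TRUE
    notes <- c(notes, paste0("missing required architecture: ",
                             paste(setdiff(required, arch), collapse = "+")))
  }
  if (is.na(motif$cys_pos)) {
    demote <- TRUE
    notes <- c(notes, "chromophore-binding Cys absent")
  }
  expected_adj <- if (klass == "RfpA") "H" else "L"
  if (!demote && !identical(motif$adj_residue, expected_adj))
    notes <- c(notes, sprintf("Cys-adjacent residue %s (expected %s for %s)",
                              motif$adj_residue, expected_adj, klass))
  final <- if (demote) "GAF-other" else klass
  best_ident <- unname(ident[[klass]])
  tibble::tibble(
    locus_tag = locus_tag, klass = final,
    architecture = paste(arch, collapse = "+"),
    gaf_identity = best_ident,
    cys_pos = motif$cys_pos,
    adj_residue = motif$adj_residue,
    triad = paste(ifelse(is.na(motif$triad), "-", motif$triad), collapse = ""),
    evidence = paste(c(motif$notes, notes), collapse = "; "))
}

#' Scan a genome for GAF photoreceptors
#'
#' Runs [find_domains()] (GAF first, then PAS/histidine-kinase architecture
#' for GAF-positive proteins) and [classify_photoreceptor()] over every
#' protein in the genome.
#'
#' @param genome A [ca_genome()].
#' @param refs Reference set.
#' @param opts Options from [ca_options()].
#' @return Tibble with one row per GAF-containing protein (columns as in
#'   [classify_photoreceptor()]); zero rows when none found.
#' @export
scan_photoreceptors <- function(genome, refs = ca_references(),
                                opts = ca_options()) {
  prots <- genome_proteins(genome)
  tbl_gaf <- refs$table[refs$table$kind == "domain" & refs$table$label == "GAF", ]
  rows <- lapply(names(prots), function(tag) {
    p <- prots[[tag]]
    row <- memo_call("scan_pr", p, opts, {
      gaf <- find_domains(p, refs, kinds = "GAF", opts = opts)
      if (nrow(gaf) == 0) list(NULL) else {
        arch <- find_domains(p, refs, kinds = c("PAS", "HisKinase"),
                             opts = opts)
        pids <- attr(gaf, "exemplar_pids")[["GAF"]]
        ident <- vapply(split(pids[tbl_gaf$name],
                              tbl_gaf$group[match(tbl_gaf$name, names(pids))]),
                        max, 1)
        list(classify_photoreceptor("", p, dplyr::bind_rows(gaf, arch),
                                    refs = refs, opts = opts,
                                    group_identity = ident))
      }
    })[[1]]
    if (is.null(row)) return(NULL)
    row$locus_tag <- tag
    row
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(locus_tag = character(0), klass = character(0),
                          architecture = character(0), gaf_identity = numeric(0),
                          cys_pos = integer(0), adj_residue = character(0),
                          triad = character(0), evidence = character(0))
  out
}
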