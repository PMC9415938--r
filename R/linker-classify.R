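# Phycobilisome linker reannotation: CpcG vs CpcL by a C-terminal
# hydrophobic-helix test, canonical vs far-red (FaRLiP) ApcE by linker-repeat
# count, chromophore-Cys presence and the PEDVT/ExACS motif.

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' @param protein Amino-acid string, length at least `window`.
#' @param window Odd window width (residues).
#' @return Object of class `ca_hydropathy`: tibble with `pos` (window centre,
#'   protein coordinate) and `score` (mean hydropathy over the window), plus
#'   attributes `locus_tag`-free `window` and `length`.
#' @export
hydropathy <- function(protein, window = 19L) {
  stopifnot(window >= 7L, window %% 2L == 1L)
  n <- nchar(protein)
  if (n < window) stop("protein shorter than hydropathy window")
  ch <- seq_chars(protein)
  v <- unname(KD_SCALE[ch])
  if (anyNA(v)) {
    warning("unknown residue symbols treated as hydropathy 0")
    v[is.na(v)] <- 0
  }
  cs <- cumsum(c(0, v))
  # rounded so threshold comparisons are stable against summation order
  scores <- round((cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window, 9)
  half <- window %/% 2L
  structure(tibble::tibble(pos = (half + 1L):(n - half), score = scores),
            window = window, protein_length = n,
            class = c("ca_hydropathy", "tbl_df", "tbl", "data.frame"))
}

#' Detect a C-terminal transmembrane segment
#'
#' Scans the profile for maximal runs of consecutive window scores at or
#' above `threshold`. A run's residue span is the stretch covered by its
#' qualifying windows (run length + window - 1 residues); runs whose span is
#' at least `min_run` residues (the minimal helix length) and overlaps the
#' last `tail_len` residues qualify, and the longest qualifying span is
#' returned.
#'
#' @param profile A [hydropathy()] profile.
#' @param tail_len C-terminal region length (residues).
#' @param threshold Minimum mean hydropathy for a window to count.
#' @param min_run Minimum residue span of the hydrophobic segment.
#' @return Integer `c(start, end)` residue span, or `NULL` when absent.
#' @export
detect_cterm_tm <- function(profile, tail_len = 60L, threshold = 1.6,
                            min_run = 15L) {
  n <- attr(profile, "protein_length")
  half <- attr(profile, "window") %/% 2L
  ok <- profile$score >= threshold
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  spans <- lapply(runs, function(i) {
    c(start = profile$pos[[starts[[i]]]] - half,
      end = profile$pos[[ends[[i]]]] + half)
  })
  spans <- spans[vapply(spans, function(s)
    s[["end"]] - s[["start"]] + 1L >= min_run, TRUE)]
  if (!length(spans)) return(NULL)
  in_tail <- vapply(spans, function(s) s[["end"]] >= n - tail_len + 1L, TRUE)
  spans <- spans[in_tail]
  if (!length(spans)) return(NULL)
  spans[[which.max(vapply(spans, function(s) s[["end"]] - s[["start"]], 1))]]
}

linker_call_row <- function(locus_tag, klass, tm_span = NULL,
                            linker_repeat_count = 0L, n_domain_cys = NA,
                            n_domain_motif = "n/a", evidence = "") {
  tibble::tibble(
    locus_tag = locus_tag, klass = klass,
    tm_start = if (is.null(tm_span)) NA_integer_ else tm_span[["start"]],
    tm_end = if (is.null(tm_span)) NA_integer_ else tm_span[["end"]],
    linker_repeat_count = linker_repeat_count,
    n_domain_cys = n_domain_cys, n_domain_motif = n_domain_motif,
    evidence = evidence)
}

#' Separate CpcL from CpcG rod linkers
#'
#' A protein carrying a phycobilisome-linker domain is CpcL when a C-terminal
#' hydrophobic helix is detected, CpcG otherwise.
#'
#' @param locus_tag Identifier.
#' @param protein Amino-acid string.
#' @param hits [find_domains()] output for this protein.
#' @param opts Options from [ca_options()].
#' @return One-row linker-call tibble (`klass` in `CpcG`, `CpcL`,
#'   `linker-other`).
#' @export
classify_rod_linker <- function(locus_tag, protein, hits, opts = ca_options()) {
  lnk <- hits[hits$domain_kind == "PBS-linker", ]
  if (nrow(lnk) == 0)
    return(linker_call_row(locus_tag, "linker-other",
                           evidence = "no PBS-linker domain hit"))
  prof <- hydropathy(protein, opts$hydro_window)
  tm <- detect_cterm_tm(prof, opts$tm_tail, opts$tm_threshold, opts$tm_min_run)
  if (is.null(tm))
    linker_call_row(locus_tag, "CpcG", linker_repeat_count = nrow(lnk),
                    evidence = "no C-terminal hydrophobic helix")
  else
    linker_call_row(locus_tag, "CpcL", tm_span = tm,
                    linker_repeat_count = nrow(lnk),
                    evidence = sprintf("C-terminal hydrophobic helix %d-%d",
                                       tm[["start"]], tm[["end"]]))
}

#' Separate FaRLiP ApcE from canonical ApcE
#'
#' Requires an N-terminal phycobiliprotein-like domain and at least one
#' linker-repeat hit. The FaRLiP form is called iff the protein has exactly
#' two linker repeats AND lacks the chromophore-binding Cys of the
#' N-terminal domain; the PEDVT (FaRLiP) vs ExACS (canonical) motif is
#' recorded as corroborating evidence, not used as a gate.
#'
#' @inheritParams classify_rod_linker
#' @param refs Reference set.
#' @return One-row linker-call tibble (`klass` in `ApcE-canonical`,
#'   `ApcE-FaRLiP`, `linker-other`).
#' @export
classify_apce <- function(locus_tag, protein, hits, refs = ca_references(),
                          opts = ca_options()) {
  pbp <- hits[hits$domain_kind == "phycobiliprotein", ]
  lnk <- hits[hits$domain_kind == "PBS-linker", ]
  if (nrow(pbp) == 0 || min(pbp$start) > 60)
    return(linker_call_row(locus_tag, "linker-other",
                           evidence = "no N-terminal phycobiliprotein domain"))
  if (nrow(lnk) == 0)
    return(linker_call_row(locus_tag, "linker-other",
                           evidence = "no linker-repeat hit"))
  pbp <- pbp[which.min(pbp$start), ]
  span <- substring(protein, pbp$start, pbp$end)
  map <- alignment_map(align_global(span, refs$seqs[[pbp$best_reference]]))
  cys_col <- diag_col(refs, "pbp", "cys")
  cc <- map[map$ref_col == cys_col, ]
  has_cys <- nrow(cc) == 1 && !is.na(cc$query_res) && cc$query_res == "C"
  mcols <- seq(diag_col(refs, "pbp", "motif_start"),
               diag_col(refs, "pbp", "motif_end"))
  mres <- vapply(mcols, function(col) {
    r <- map[map$ref_col == col, ]
    if (nrow(r) == 0 || is.na(r$query_res)) "-" else r$query_res
  }, "")
  mstr <- paste(mres, collapse = "")
  motif <- if (mstr == "PEDVT") "PEDVT"
           else if (grepl("^E.ACS$", mstr)) "ExACS"
           else "other"
  n_rep <- nrow(lnk)
  farlip <- n_rep == 2L && !has_cys
  notes <- sprintf("%d linker repeats; N-domain Cys %s; motif %s", n_rep,
                   if (has_cys) "present" else "absent", mstr)
  if (farlip && motif != "PEDVT")
    notes <- paste0(notes, "; motif discordant with FaRLiP call")
  if (!farlip && n_rep == 2L && has_cys)
    notes <- paste0(notes, "; two repeats but Cys present (discordant)")
  linker_call_row(locus_tag, if (farlip) "ApcE-FaRLiP" else "ApcE-canonical",
                  linker_repeat_count = n_rep, n_domain_cys = has_cys,
                  n_domain_motif = motif, evidence = notes)
}

#' Classify all linker-domain proteins of a genome
#'
#' Proteins with a phycobilisome-linker domain hit are routed to the ApcE
#' branch when they also carry an N-terminal phycobiliprotein-like domain,
#' and to the rod-linker (CpcG/CpcL) branch otherwise.
#'
#' @param genome A [ca_genome()].
#' @param refs Reference set.
#' @param opts Options from [ca_options()].
#' @return Tibble of linker calls, one row per linker-domain protein.
#' @export
classify_linkers <- function(genome, refs = ca_references(),
                             opts = ca_options()) {
  prots <- genome_proteins(genome)
  rows <- lapply(names(prots), function(tag) {
    p <- prots[[tag]]
    row <- memo_call("linker", p, opts, {
      lnk <- find_domains(p, refs, kinds = "PBS-linker", opts = opts)
      if (nrow(lnk) == 0) list(NULL) else {
        pbp <- find_domains(p, refs, kinds = "phycobiliprotein", opts = opts)
        hits <- dplyr::bind_rows(lnk, pbp)
        if (nrow(pbp) > 0 && min(pbp$start) <= 60)
          list(classify_apce("", p, hits, refs, opts))
        else
          list(classify_rod_linker("", p, hits, opts))
      }
    })[[1]]
    if (is.null(row)) return(NULL)
    row$locus_tag <- tag
    row
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- linker_call_row(character(0), character(0))[0, ]
  out
}
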