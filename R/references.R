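# Packaged reference set. The exemplars are synthetic stand-ins constructed
# to carry the diagnostic features of the real photoreceptor and linker
# families (chromophore-binding Cys, His/Leu adjacency, protochromic-triad
# columns, PEDVT/ExACS motifs, C-terminal transmembrane tail); see the
# methods vignette for how they were built.

#' Load the packaged reference exemplars
#'
#' @return A list with:
#'   * `table`: tibble of exemplar metadata (`name`, `kind`, `label`,
#'     `group`, `length`, `frozen` positions),
#'   * `seqs`: named character vector of amino-acid sequences,
#'   * `diagnostics`: tibble mapping profile features (GAF cys/adjacent/triad
#'     columns, phycobiliprotein cys and motif window) to reference columns,
#'   * `kmers`: per-exemplar 4-mer sets used by the alignment prescreen.
#' @export
ca_references <- function() {
  if (!is.null(.catyper_cache$refs)) return(.catyper_cache$refs)
  dir <- system.file("extdata", "references", package = "catyper",
                     mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(file.path(dir, "synthetic_references.faa"))
  seqs <- stats::setNames(as.character(aa), sub("\\s.*", "", names(aa)))
  tbl <- tibble::as_tibble(utils::read.delim(
    file.path(dir, "synthetic_references.tsv"), stringsAsFactors = FALSE,
    na.strings = ""))
  tbl$frozen <- lapply(tbl$frozen, function(x) {
    if (is.na(x) || !nzchar(x)) integer(0) else as.integer(strsplit(x, ",")[[1]])
  })
  diagn <- tibble::as_tibble(utils::read.delim(
    file.path(dir, "diagnostic_columns.tsv"), stringsAsFactors = FALSE))
  refs <- list(table = tbl, seqs = seqs, diagnostics = diagn,
               kmers = lapply(seqs, protein_kmers))
  .catyper_cache$refs <- refs
  refs
}

# exemplar names for a domain kind / gene label
ref_names <- function(refs, kind = NULL, label = NULL) {
  tbl <- refs$table
  if (!is.null(kind)) tbl <- tbl[tbl$kind == "domain" & tbl$label == kind, ]
  if (!is.null(label)) tbl <- tbl[tbl$kind == "gene" & tbl$label == label, ]
  tbl$name
}

diag_col <- function(refs, profile, feature) {
  d <- refs$diagnostics
  d$column[d$profile == profile & d$feature == feature]
}

#' Default analysis thresholds
#'
#' Every cut-off used by the scanners in one place, so a run can snapshot its
#' configuration. Values are package defaults, validated by the synthetic
#' recovery properties.
#'
#' @param ... Named overrides of individual defaults.
#' @return Named list of options.
#' @export
ca_options <- function(...) {
  opts <- list(
    detect_identity = 25,   # % identity to call a domain hit
    assign_identity = 40,   # % GAF identity to assign a receptor group
    label_identity = 50,    # % identity to label a gene after an exemplar
    span_window = c(0.6, 1.4),  # admissible hit span relative to exemplar length
    kmer_k = 4L,
    kmer_min = 0.05,        # prescreen: min fraction of exemplar k-mers shared
    hydro_window = 19L,
    tm_threshold = 1.6,
    tm_min_run = 15L,
    tm_tail = 60L,
    operon_gap = 150L,      # max intergenic bp within an operon
    context_k = 5L,
    jtt_max_dist = 10,
    max_hits = c(GAF = 2L, PAS = 1L, HisKinase = 1L,
                 "PBS-linker" = 4L, phycobiliprotein = 1L)
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(opts)))
  utils::modifyList(opts, over)
}

# Session-scoped memoisation for per-protein scan results: identical inputs
# (protein, stage, options) always produce identical outputs, so repeated
# cohort members are computed once.
memo_call <- function(stage, protein, opts, expr) {
  if (is.null(.catyper_cache$memo))
    .catyper_cache$memo <- new.env(parent = emptyenv())
  key <- rlang::hash(list(stage, protein, opts))
  hit <- .catyper_cache$memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .catyper_cache$memo[[key]] <- val
  val
}
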