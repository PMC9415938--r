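# Combine photoreceptor calls, linker calls, cluster detection and the
# phycobiliprotein/bilin gene inventory into per-genome chromatic
# acclimation (CA) type assignments.

#' Build the phycobilisome / bilin gene inventory of a genome
#'
#' @param genome A [ca_genome()].
#' @param labels [label_genes()] output.
#' @param linker_calls [classify_linkers()] output.
#' @return One-row tibble: `genome_id`, `has_apc`, `has_pc`, `has_pe`,
#'   `has_pec`, `peb_capable` (pebA AND pebB), `n_apcE`, `n_cpcG`, `n_cpcL`,
#'   `apcE_farlip_present`.
#' @export
build_inventory <- function(genome, labels, linker_calls) {
  lab <- labels$label
  kl <- linker_calls$klass
  tibble::tibble(
    genome_id = genome$genome_id,
    has_apc = any(lab %in% c("apcD", "apcB", "apcE")),
    has_pc = any(lab %in% c("cpcA", "cpcB")),
    has_pe = any(lab %in% c("cpeA", "cpeB")),
    has_pec = any(lab %in% c("pecA", "pecB")),
    peb_capable = any(lab == "pebA") && any(lab == "pebB"),
    n_apcE = sum(kl %in% c("ApcE-canonical", "ApcE-FaRLiP")),
    n_cpcG = sum(kl == "CpcG"),
    n_cpcL = sum(kl == "CpcL"),
    apcE_farlip_present = any(kl == "ApcE-FaRLiP"))
}

ca_rules <- function(photoreceptors, inv, farlip_present) {
  pr <- photoreceptors
  list(
    CA1 = list(fired = ("CcaS" %in% pr) && inv$n_cpcL >= 1,
               rule = "CcaS AND >=1 CpcL",
               predicates = sprintf("CcaS=%s, n_cpcL=%d",
                                    "CcaS" %in% pr, inv$n_cpcL)),
    CA2 = list(fired = ("CcaS" %in% pr) && inv$has_pe && inv$peb_capable,
               rule = "CcaS AND PE genes AND PEB synthesis (pebA+pebB)",
               predicates = sprintf("CcaS=%s, has_pe=%s, peb=%s",
                                    "CcaS" %in% pr, inv$has_pe, inv$peb_capable)),
    CA3 = list(fired = ("RcaE" %in% pr) && inv$has_pe && inv$peb_capable,
               rule = "RcaE AND PE genes AND PEB synthesis (pebA+pebB)",
               predicates = sprintf("RcaE=%s, has_pe=%s, peb=%s",
                                    "RcaE" %in% pr, inv$has_pe, inv$peb_capable)),
    CA6 = list(fired = farlip_present,
               rule = "FaRLiP cluster (rfpBAC operon AND apcD-E-D-B-D block)",
               predicates = sprintf("farlip=%s", farlip_present)),
    CA7 = list(fired = ("CcaS" %in% pr) && inv$has_pec,
               rule = "CcaS AND PEC genes",
               predicates = sprintf("CcaS=%s, has_pec=%s",
                                    "CcaS" %in% pr, inv$has_pec)))
}

#' Assign chromatic acclimation types to a genome
#'
#' The decision rules: CA1 = CcaS plus at least one CpcL rod-membrane
#' linker; CA2 = CcaS plus phycoerythrin genes plus PEB synthesis capability
#' (pebA and pebB); CA3 = the same phycoerythrin conditions under RcaE; CA6
#' = an assembled FaRLiP cluster; CA7 = CcaS plus phycoerythrocyanin genes.
#' Rules fire independently; a genome matching none is non-CA. An RfpA-like
#' photoreceptor without a FaRLiP cluster yields a warning and no CA6.
#'
#' @param photoreceptors Character subset of `c("CcaS", "RcaE", "RfpA")`.
#' @param inventory One-row tibble from [build_inventory()].
#' @param farlip [assemble_farlip()] result or `NULL`.
#' @return One-row tibble: `genome_id`, `photoreceptors` (slash-joined),
#'   `ca_types` (list column), `non_ca`, and a `trace` list column recording
#'   each rule's predicates and outcome.
#' @export
assign_ca <- function(photoreceptors, inventory, farlip = NULL) {
  if ("RfpA" %in% photoreceptors && is.null(farlip))
    warning("RfpA-like photoreceptor without a detectable FaRLiP cluster in ",
            inventory$genome_id, "; regulatory function unknown, no CA6")
  rules <- ca_rules(photoreceptors, inventory, !is.null(farlip))
  trace <- tibble::tibble(
    ca_type = names(rules),
    rule = unname(vapply(rules, `[[`, "", "rule")),
    predicates = unname(vapply(rules, `[[`, "", "predicates")),
    fired = unname(vapply(rules, `[[`, TRUE, "fired")))
  types <- trace$ca_type[trace$fired]
  tibble::tibble(
    genome_id = inventory$genome_id,
    photoreceptors = paste(intersect(c("CcaS", "RcaE", "RfpA"),
                                     photoreceptors), collapse = "/"),
    ca_types = list(types),
    non_ca = length(types) == 0L,
    trace = list(trace))
}

#' Summarise CA assignments across a cohort
#'
#' @param profiles Row-bound [assign_ca()] results (one row per genome).
#' @return One-row tibble of cohort counts: per-photoreceptor, pairwise and
#'   triple co-existence, per CA type, non-CA, and green/red-capable
#'   genomes (any of CA1, CA2, CA3, CA7).
#' @export
cohort_summary <- function(profiles) {
  if (nrow(profiles) == 0) stop("empty cohort")
  if (anyDuplicated(profiles$genome_id))
    stop("duplicate genome_id in cohort: ",
         paste(unique(profiles$genome_id[duplicated(profiles$genome_id)]),
               collapse = ", "))
  has_pr <- function(p) vapply(strsplit(profiles$photoreceptors, "/"),
                               function(x) p %in% x, TRUE)
  has_ca <- function(ca) vapply(profiles$ca_types, function(x) ca %in% x, TRUE)
  ccas <- has_pr("CcaS"); rcae <- has_pr("RcaE"); rfpa <- has_pr("RfpA")
  tibble::tibble(
    n_genomes = nrow(profiles),
    n_ccas = sum(ccas), n_rcae = sum(rcae), n_rfpa = sum(rfpa),
    n_ccas_rcae = sum(ccas & rcae),
    n_ccas_rfpa = sum(ccas & rfpa),
    n_rcae_rfpa = sum(rcae & rfpa),
    n_all_three = sum(ccas & rcae & rfpa),
    n_ca1 = sum(has_ca("CA1")), n_ca2 = sum(has_ca("CA2")),
    n_ca3 = sum(has_ca("CA3")), n_ca6 = sum(has_ca("CA6")),
    n_ca7 = sum(has_ca("CA7")),
    n_non_ca = sum(profiles$non_ca),
    n_green_red = sum(has_ca("CA1") | has_ca("CA2") | has_ca("CA3") |
                        has_ca("CA7")))
}
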