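# Low-level sequence utilities shared by the reference set, the synthetic
# genome generator and the scanners.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' Sample a random protein sequence
#'
#' Residues are drawn independently from the JTT equilibrium amino-acid
#' frequencies, giving decoy open reading frames a realistic composition.
#'
#' @param n Protein length (residues).
#' @param freqs Named amino-acid frequency vector; defaults to the packaged
#'   JTT equilibrium frequencies.
#' @return A single amino-acid string.
#' @export
random_protein <- function(n, freqs = jtt_model()$freq) {
  chars_seq(sample(names(freqs), n, replace = TRUE, prob = freqs))
}

#' Mutate a protein at a fixed per-site substitution probability
#'
#' Replacement residues are sampled proportionally to the JTT
#' exchangeability-times-frequency weight of the original residue, so
#' diverged copies remain recognisable homologs rather than random strings.
#' Positions listed in `frozen` (diagnostic columns such as the
#' chromophore-binding cysteine) are never touched.
#'
#' @param protein Amino-acid string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param frozen Integer positions exempt from mutation.
#' @return The mutated amino-acid string.
#' @export
mutate_protein <- function(protein, rate, frozen = integer(0)) {
  if (rate <= 0) return(protein)
  m <- jtt_model()
  ch <- seq_chars(protein)
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, frozen)
  for (i in hit) {
    a <- ch[i]
    if (!a %in% m$aa) next
    w <- m$S[a, ] * m$freq
    w[a] <- 0
    ch[i] <- sample(m$aa, 1, prob = w)
  }
  chars_seq(ch)
}

# Unique k-mers of a sequence (used as an alignment prescreen seed set).
protein_kmers <- function(x, k = 4L) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1L), k:n))
}

# Fraction of the query's k-mers present in the reference k-mer set.
kmer_containment <- function(query_kmers, ref_kmers) {
  if (length(query_kmers) == 0) return(0)
  sum(query_kmers %in% ref_kmers) / length(query_kmers)
}

# --- nucleotide helpers -----------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein to a coding sequence
#'
#' Synonymous codons are drawn uniformly at random (seed-controlled by the
#' caller), and a random stop codon is appended.
#'
#' @param protein Amino-acid string.
#' @return Nucleotide string of length `3 * (nchar(protein) + 1)`.
#' @export
reverse_translate <- function(protein) {
  ct <- codon_table()
  ch <- seq_chars(protein)
  codons <- vapply(ch, function(a) {
    opts <- ct[[a]]
    if (is.null(opts)) "NNN" else sample(opts, 1)
  }, "", USE.NAMES = FALSE)
  stop <- sample(ct[["*"]], 1)
  paste0(paste(codons, collapse = ""), stop)
}

random_dna <- function(n) {
  chars_seq(sample(c("A", "C", "G", "T"), n, replace = TRUE))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_cds <- function(nt) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
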