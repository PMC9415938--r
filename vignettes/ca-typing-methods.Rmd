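---
title: "Genome-based typing of cyanobacterial chromatic acclimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based typing of cyanobacterial chromatic acclimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catyper)
```

# The scientific problem

Cyanobacteria remodel their phycobilisome (PBS) antenna in response to the
ambient light colour, a family of responses called chromatic acclimation
(CA). The acclimation variants CA1, CA2, CA3, CA6 and CA7 are each governed
by a GAF-domain photoreceptor — CcaS (CA1/CA2/CA7), RcaE (CA3) or RfpA (CA6,
far-red light photoacclimation, FaRLiP) — acting on a matching set of PBS
components: the rod–membrane linker CpcL, phycoerythrin (PE) rods plus the
phycoerythrobilin (PEB) synthesis enzymes PebA/PebB, phycoerythrocyanin
(PEC), or the dedicated FaRLiP gene cluster. Because every ingredient is a
gene product, CA capability can be *predicted from genome content alone*:
find the photoreceptors, reannotate the linker proteins, check the bilin
synthesis genes, detect the FaRLiP cluster, and combine the evidence.

`catyper` implements that screening procedure as a set of composable,
tibble-first functions plus an orchestrating pipeline, and ships a
synthetic-genome generator that provides ground truth for every stage.

# Photoreceptor classification

GAF-containing proteins are found by local alignment (BLOSUM62,
affine gaps) of packaged GAF exemplars against each proteome; hits need at
least 25% identity over a domain-scale span. Candidate photoreceptors are
then assigned to CcaS, RcaE or RfpA by the highest per-group GAF identity,
and *demoted to "GAF-other"* when any of three conditions fails:

* best group identity below 40%,
* required domain architecture absent (PAS + GAF + histidine kinase for
  RfpA; GAF + histidine kinase for CcaS/RcaE),
* chromophore-binding cysteine absent from the aligned reference column.

The residue adjacent to the chromophore Cys (His in RfpA, Leu in CcaS and
RcaE) and the protochromic-triad residues are extracted by a global
alignment of the hit span to its best exemplar. They are recorded as
evidence, and used only to break exact identity ties — classification by
similarity first, motifs as corroboration.

The 25%/40% cut-offs are package defaults (`ca_options()`), chosen at the
conventional twilight-zone boundary for domain-scale alignments and
validated by the synthetic recovery properties in the test suite; no
published cut-off exists for this screening procedure.

# Linker reannotation

Both rod–core (CpcG) and rod–membrane (CpcL) linkers carry the same PBS
linker domain, so annotation cannot separate them. The discriminating
feature is a C-terminal hydrophobic helix in CpcL. We compute a windowed
Kyte–Doolittle hydropathy profile (window 19) and call a transmembrane
anchor when a run of windows at mean hydropathy ≥ 1.6 covers at least 15
residues (a minimal-helix-length criterion) and overlaps the last 60
residues. All four constants are configurable; with the default 19-residue
window any qualifying run already spans ≥ 19 residues, so the helix-length
floor matters when narrower windows are configured. The rule is
deliberately binary — presence/absence of a C-terminal anchor — matching
how the original screening used transmembrane predictions.

ApcE, the core–membrane linker, has an N-terminal phycobiliprotein-like
domain followed by repeated linker domains. The far-red (FaRLiP) ApcE is
called when the protein has **exactly two** linker repeats **and** lacks
the chromophore-binding Cys of the N-terminal domain; the PEDVT (FaRLiP)
versus ExACS (canonical) motif at the packaged reference columns is
recorded as corroborating evidence but is not a gate, and discordant
combinations (two repeats with Cys present, or more than two repeats) are
flagged rather than forced. Linker repeats are counted as non-overlapping
domain hits found by iterated local alignment with masking.

# FaRLiP cluster detection

The FaRLiP call is synteny-based: a genome must carry

* the three-gene operon rfpB–rfpA–rfpC — three consecutive, co-stranded
  genes with intergenic gaps ≤ 150 bp, read in either orientation, and
* the five-gene allophycocyanin block apcD–apcE–apcD–apcB–apcD, with a
  single extra apcD tolerated and flagged (one known genome carries six).

"Operon" is operationalised as consecutive co-stranded genes with ≤ 150 bp
gaps, the standard prokaryotic heuristic; the source procedure never
defines it formally. The two parts may sit on different contigs
(scaffold-split clusters are recorded, not rejected). Photosystem (psaA/B,
psbA–D) and chlorophyll-f synthase (chlF) content is attached as evidence
with anomalies logged as notes — one known FaRLiP genome has a truncated
PsaB, so photosystem completeness must not be a gate. A genome with an
RfpA-like photoreceptor but no detectable cluster is reported "RfpA-like,
function unknown" and never assigned CA6.

# CA assignment rules

The decision table, applied independently per rule:

| type | rule |
|------|------|
| CA1 | CcaS ∧ ≥ 1 CpcL |
| CA2 | CcaS ∧ PE genes (cpeA/cpeB) ∧ PEB capability (pebA ∧ pebB) |
| CA3 | RcaE ∧ PE genes ∧ PEB capability |
| CA6 | FaRLiP cluster assembled |
| CA7 | CcaS ∧ PEC genes (pecA/pecB) |

A genome matching no rule is non-CA, with the full predicate trace retained
so that future rules (the CA4/CA5 photoreceptors are still undefined) can
be added without re-screening. Two deliberate asymmetries: CA1 does not
require absence of PE (known genomes are CA1+CA2 simultaneously), and CA7
does not require PE at all (the known CA7 representative lacks it). CA2
uses PE plus PEB capability rather than specific PE-rod linker genes; a
stricter linker-based CA2 rule would need evidence the screening procedure
never states.

# Phylogenetics

Trees serve one purpose here: verifying that the three receptor groups are
phylogenetically coherent. Multiple alignment goes through MAFFT; pairwise
distances are maximum-likelihood estimates under the JTT amino-acid model
with equal rates across sites (the exchangeabilities and equilibrium
frequencies ship as a plain-text data file), obtained by one-dimensional
likelihood maximisation on pairwise-deleted columns; trees are built by
neighbor joining with label-sorted tie-breaking, negative branch lengths
clamped to zero, and bootstrap support computed by column resampling.
Distances that reach the saturation cap (10 substitutions/site) are capped
and flagged. Gap handling is pairwise deletion by default — complete
deletion would discard most columns in sparse alignments. The acceptance
surface for tree code is structural (topology recovery on additive
matrices, oracle equivalence of the ML distance, three-group recovery),
not branch-length identity to any particular legacy program.

# The synthetic cohort: what it does and does not emulate

No public sequence database is bundled, so the packaged references are
**synthetic exemplars**: random proteins of realistic composition (JTT
equilibrium frequencies) into which the diagnostic features are written
explicitly — a conserved Cys with His/Leu adjacency and group-specific
triad residues in the GAF domains, PEDVT/ExACS motifs and the chromophore
Cys in the ApcE N-domain, a 21-residue hydrophobic tail in CpcL, and
distinct exemplars for every labelled gene (rfpB/C, apc, psa/psb, chlF,
peb, cpe, pec, cpc families). Receptor groups were diverged far enough
that between-group GAF identity (25–32%) sits below the 40% assignment
threshold while within-group identity stays high (≥ 87%).

The generator embeds diverged copies of these exemplars into multi-contig
genomes: substitutions are sampled with JTT exchangeability weighting
(uniform mutation would make realistic divergence levels unrecognisable),
diagnostic columns are frozen unless a negative-control fixture asks
otherwise, FaRLiP genes are laid out with operon-scale gaps (60–120 bp)
and optionally split across contigs, and decoy ORFs — including
GAF-containing decoys with a substituted chromophore Cys — pad each
genome. Specifications validate at construction time: a declared truth
label that contradicts the implied rule outcome is an error, so fixtures
can never disagree with their truth table.

What passing synthetic tests shows: the screening logic, the synteny
detector, the numerical primitives and the rule table behave correctly on
inputs whose ground truth is known by construction, across divergence up
to 30% per site. What it does not show: performance on real annotation
noise (fragmented assemblies, frameshifted or missed gene calls, paralog
families not represented among the exemplars), real domain-length
variation, or indel-rich divergence — the generator mutates by
substitution only. Published cohort-level numbers require the original
public genomes and are deliberately not asserted by the test suite.

# Numerical choices and degenerate inputs

* Window hydropathy scores are rounded to 9 decimals so threshold
  comparisons do not depend on summation order.
* Iterated-masking domain search caps hits per kind (2 GAF, 4 linker
  repeats) — tandem-GAF cyanobacteriochromes are out of scope.
* The ML distance of identical rows is exactly 0 by construction; rows
  with no shared ungapped columns are an error, not an NA.
* Per-protein scan results are memoised within a session (same protein,
  same options ⇒ same call), which makes zero-divergence cohorts cheap
  without affecting results.
* Problem sizes in the validation suite — 200-genome cohorts, 500
  bootstrap replicates, 500-protein oracle sweeps — were chosen as the
  smallest sizes at which the recovery and support statistics are stable.

# Known limitations

* CA4 and CA5 are never assigned; their photoreceptors are undefined.
* Cyanobacteriochrome fine-tuning receptors (e.g. DpxA) are out of scope.
* Compound (joined) gene locations are collapsed to min–max spans; synteny
  uses gene order only, so this is harmless downstream.
* The reference set is synthetic; applying the package to real genomes
  requires swapping in curated exemplar FASTA/metadata files of the same
  layout (`inst/extdata/references/`).
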