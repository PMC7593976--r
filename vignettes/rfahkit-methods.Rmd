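---
title: "rfahkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rfahkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

NusG is the only transcription elongation factor conserved across all
bacteria; it travels with RNA polymerase and, among other things, couples
transcription to Rho-dependent termination. Some lineages additionally carry
specialized paralogs (NusG^SP^: RfaH, UpxY, LoaP and others) that are
recruited to specific operons and often antagonize the housekeeping factor's
functions. Tracing how such a paralog arises — duplication of the
housekeeping gene, loss of old interactions, gain of new ones, horizontal
spread — requires a pipeline that combines profile-model homology search,
orthology detection, sequence clustering, tree congruence and genomic
context analysis.

`rfahkit` implements that pipeline as reusable, tested components and pairs
it with a synthetic genome-world generator. The generator plants the
evolutionary structure the pipeline is supposed to detect, so every stage
can be scored against an exact ground truth without downloading any
database. Real analyses can use the same components on real proteomes; the
synthetic world is the test harness, not the object of study.

# The synthetic genome world

`world_config()` / `build_world()` create a set of genomes with:

* a **species tree**: a pure-birth (Yule) tree rescaled to a root-to-tip
  height of 0.3 expected substitutions/site, with a minimum branch length of
  0.05. The floor guarantees that every split carries roughly
  `0.05 x 300 = 15` expected substitutions in a single-family alignment, so
  single-gene trees can recover the full topology; the price is that the
  tree is ultrametric only approximately. Slicing the tree at the time when
  exactly `n_clades` lineages exist defines the clades ("classes" of the
  taxonomy).
* a **housekeeping family** (NusG-like, 300 aa) evolved on the species tree
  at rate 1, present in every genome except the reduced ones, always inside
  the conserved operon context secE -> nusG -> rplK -> rplA (consecutive
  genes, one strand).
* a **paralog family** (RfaH-like) split into subfamilies. The paralog
  ancestor sits 1.6 subs/site from the housekeeping ancestor (about 20%
  identity, the NusG-vs-RfaH regime); subfamily ancestors radiate 0.6
  subs/site from it; within a subfamily, members evolve on their clade's
  subtree rescaled to a crown height of 0.08 and multiplied by the family
  rate factor 3. The paralog thus radiated *after* its host clades, which is
  also what keeps subfamilies separable at the clustering cutoffs.
  Horizontal transfers copy a donor-subfamily lineage into a genome outside
  the donor clade; duplications add a second, slightly diverged in-genome
  copy.
* an **"unknown" family**: a sister lineage 0.7 subs/site from the paralog
  ancestor, present in a few genomes. It is deliberately left out of the
  curated positive/negative sets, which is what places it between the
  trusted and noise cutoffs of the final paralog model (the "candidate"
  zone an annotator would flag for manual review).
* **seven single-copy control families** (secE, rplK, rplA, recA, rplE,
  rplF, rpsB stand-ins), independent ancestors evolved at rate 1 — the
  markers for the concatenated genome tree and the completeness screen.
* **functional sites**: ten positions (E. coli RfaH numbering: K10, E48,
  F56, R73, F81, I93, F130, L145-I146-N147) held fixed at RfaH-state
  residues in every paralog and at divergent residues in the housekeeping
  family. They drive the conserved-position filter during model extension
  and the site-state maps.
* **decoys**: i.i.d. random proteins, lengths uniform in [80, 300],
  residues drawn from natural (Robinson & Robinson) amino-acid frequencies.
  Natural composition matters: the analytic E-value constants
  (lambda = 0.267, K = 0.041) are calibrated for it, so chance-alignment
  statistics behave like BLAST's. Decoy COG categories are uniform over the
  20 standard letters with 10% unassigned; the 5-gene windows around each
  paralog copy are enriched for a subfamily-specific category
  (CL1 -> M, CL2 -> G, CL3 -> T at 60% adoption), the planted signal of the
  neighborhood analysis.
* two **reduced genomes** that keep all controls but lack the housekeeping
  gene — emulating genuinely streamlined genomes rather than broken
  assemblies, and exercised by the completeness screen and the
  gapped-operon report.

Determinism: a single integer seed drives everything through label-keyed
sub-streams (`substream_seed()`), so identical configs give byte-identical
FASTA/TSV output and adding one genome does not reshuffle the others.

What the generator does **not** emulate: indels within families (family
alignments are exact stacks by construction), codon-level processes, domain
architecture (real NusG-family proteins are two-domain NGN+KOW), gene order
rearrangements beyond random placement, compositional heterogeneity across
sites, and assembly artifacts. Passing tests therefore demonstrate that the
pipeline's logic recovers planted structure under a clean substitution
process — not that it is robust to alignment error or annotation noise in
real data.

# Pairwise alignment and E-values

`global_align()` / `local_align()` are exact affine-gap dynamic programs
(Needleman-Wunsch, Smith-Waterman) over BLOSUM62 with the BLAST default
penalties: a gap of length L costs `11 + L`. Traceback tie-breaks are fixed
(substitution > gap-in-subject > gap-in-query; closing a gap beats
extending) so alignments are byte-reproducible. Percent identity divides
identities by the *shorter* sequence length — the CD-HIT convention, chosen
because the redundancy-reduction steps reproduce CD-HIT usage (95% and 80%
levels).

E-values use the analytic Karlin-Altschul form `E = K m n exp(-lambda S)`
with fixed gapped-BLOSUM62 constants and no edge-effect or composition
correction. This is a calibration stand-in: E-values are in the right
regime but will not match NCBI BLAST digit-for-digit, and any conclusion
that hinges on a hit sitting within a factor of a few of a cutoff should be
treated as fragile. One measurable consequence: with a correctly calibrated
tail, a best-hit threshold of 1e-5 *will* pass roughly `N x 1e-5` chance
hits in N random comparisons, so an all-vs-all sweep over many genome pairs
occasionally yields a spurious reciprocal pair of decoys. That is the
statistics working as specified, not a defect.

# Profile models

`build_profile()` estimates a match/insert/delete profile from an
alignment: columns with gap fraction at most 0.5 become match states
(HMMER-like default; stated explicitly because no single convention is
universal). Match emissions use a +background pseudocount,
`P(a) = (count_a + bg_a) / (n_obs + 1)` with a uniform background of 0.05
per residue (configurable; uniform keeps bit scores reproducible without
external frequency tables). Transitions are estimated from the observed
per-row state paths with one total pseudocount spread by a standard prior
(M: 0.9/0.05/0.05, I: 0.7/0.3, D: 0.7/0.3). There is no insert state before
the first or after the last match column.

`score_sequence()` is a glocal Viterbi: the model is traversed end to end,
while sequence flanks outside the model are free and null-scored, giving
log2-odds bits against the background null. Glocal mode suits the use case
— family members are near-full-length — and avoids the extra machinery of
full local entry/exit. The kernel is verified against exhaustive state-path
enumeration on small models.

Cutoffs follow the Pfam convention (`calibrate_cutoffs()`): trusted = the
lowest score of a curated member, noise = the highest score of a curated
non-member. Scores at or above trusted are members, scores at or below
noise are nothing, and the open interval between is the candidate zone.
`build_family_model()` reproduces the whole workflow: seed alignment,
initial profile, pool scan, extension filtered by positive bits *plus*
required residues at the configured conserved sites (the automated stand-in
for a manual structure-informed screen), redundancy reduction at 80%
identity, re-alignment, final profile, calibration.

# Clustering

`stepwise_cluster()` chains three steps. Redundancy reduction is greedy
incremental clustering at 95% identity (length-sorted, first-fit — the
CD-HIT scheme without its word-filter heuristics). The similarity graph
admits an edge only when *both* directional E-values pass `<= 5e-30` and
coverage is `>= 80%` on *both* sequences — the strictest reading of an
ambiguous protocol, and configurable. Edge weights store the average of the
two reciprocal E-values; since Markov clustering needs larger-is-closer,
the weight actually used is `-log10(mean E)` floored at 1e-180. This
log-transform is the main interpretive choice in the module.

`mcl()` is a from-scratch dense implementation: self-loops at each node's
maximum incident weight (standard stabilization; isolated nodes get 1),
column normalization, then alternating expansion (matrix square) and
inflation (entrywise 5th power at the default inflation of 5) with pruning
of entries below 1e-6 *after* renormalization — pruning after normalization
means a column can never empty. Convergence is a max-entry change below
1e-8. Clusters are connected components of the attractor structure; nodes
attracted to several clusters go to the larger attractor mass. Labels are
deterministic (size, then smallest member). All clusters are reported;
nothing is folded into an "other" bin.

# Trees

All tree inference is distance-based: Poisson-corrected p-distances with
pairwise gap deletion (`d = -ln(1 - min(p, 0.95))`), then neighbor joining
(via `ape`, negative branch lengths clamped to zero). This replaces the
maximum-likelihood inference a production analysis would use; only
topology-level conclusions are drawn (Robinson-Foulds congruence), never
branch-length-calibrated dates. The Robinson-Foulds distance is the size of
the symmetric split difference, normalized by the total number of internal
splits present. The rate comparison uses the tree diameter — the maximal
leaf-to-leaf branch-length sum — because a root-independent statistic is
preferable for unrooted NJ trees; a root-to-leaf variant is available
(`longest_path_sum(t, from_root = TRUE)`).

The HGT signal is the classical one: the concatenated-marker genome tree
matches the housekeeping gene tree exactly (RF = 0), while the paralog tree
conflicts with it (RF > 0) because transferred genes sit with their donor
subfamily, not their host genome. One caveat the tests encode: a *single*
transfer whose recipient attaches as an outgroup of the donor subfamily can
be topologically invisible; the property is only guaranteed with several
planted transfers.

# Sites, profiles and neighborhoods

`map_positions()` translates 1-based ungapped reference numbering into
alignment columns; `annotate_states()` classifies each sequence at each
site as identical, conservative, divergent or gap. "Conservative" uses a
fixed physico-chemical partition ({K,R,H} {D,E} {N,Q} {S,T} {I,L,V,M}
{F,W,Y} {A,G} {C} {P}) — the source display convention never defines one,
so a standard partition is used and is configurable.

`presence_matrix()` counts member-zone hits only (candidates are not
presence). `percent_hits()` reports per-taxon hit percentages for taxa with
at least 10 genomes. `completeness_screen()` lists genomes with no focal
hit but hits for every control marker — distinguishing true absence from
incomplete data. `operon_context()` reports conserved-operon loci as intact
or gapped; at protein level a pseudogenized gene and a deleted gene are
both "gapped" (nucleotide-level frameshift inspection is out of scope).

`cog_matrix()` pools the COG categories of up to five genes on each side of
each clustered focal gene (strand-agnostic windows, focal genes excluded
from their own windows, truncation at contig ends), normalized per cluster
by the number of focal genes; `cog_percentages()` row-normalizes raw counts
instead.

# Problem sizes and reproducibility

The default study conditions are 40 genomes in 4 clades (about 1,550
proteins), paralog presence 0.6 with 3 subfamilies, 3 transfers, 2
duplications, 2 reduced genomes and 30 decoys per genome. At these sizes a
full `run_all()` takes well under a minute on one CPU; the test suite
builds several such worlds and stays around a minute. The
reciprocal-best-hit evaluation samples genome pairs (40 by default in
`run_config()`) rather than sweeping all 780 — the recall estimate is
unchanged and the cost drops by an order of magnitude.

Everything is deterministic given the seed; stages derive sub-seeds from it
so results are stable under reordering. `scripts/acceptance.R` recomputes
the headline quantities (clustering ARI, ortholog recall, cutoff margins
and zone rates, tree congruence, diameter ratio, oracle agreement,
neighborhood recovery) from scratch for any seed.

# Known limitations

* The E-value model ignores edge effects and composition; absolute values
  differ from BLAST, and cutoff-adjacent decisions are fragile.
* Center-star alignment is exact only in the no-indel regime the generator
  produces; on real, indel-rich families a progressive aligner would be
  preferable, and the profile's match-column choice would start to matter.
* NJ on Poisson distances saturates near p = 0.95; deep relationships
  (e.g., paralog ancestor vs housekeeping family) are outside the reliable
  range and are never interpreted.
* The MCL implementation is dense (O(n^2) memory) and intended for up to a
  few thousand representatives.
* Site-state collapsing for display and ancestral-state reconstruction are
  not implemented.
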