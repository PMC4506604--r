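---
title: "Methods: mapping, clustering and pocket detection in structvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping, clustering and pocket detection in structvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structvar)
```

## The problem

A protein that carries several missense variants at once is more than the sum
of its single substitutions: residues far apart in sequence can sit a few
Angstrom apart in the folded structure, line the same binding cleft, or pack
into the same hydrophobic core. structvar takes a list of non-synonymous
variants for a protein, places each one on a three-dimensional structure, and
derives the quantities a curator needs to shortlist candidates: spatial
clusters of mutated residues, proximity to putative ligand-binding pockets,
known pathogenicity labels, and a predicted direction of stability change.
The output is an HTML information page plus machine-readable tables and a
flagged coordinate file that any molecular viewer can colour by cluster.

## Variant input and canonical form

Three input dialects are parsed into one canonical record per substitution
(gene, wild-type residue, 1-based protein position, mutant residue, optional
hg19 genomic coordinates, optional preferred structure):

* a simple tab-separated table with `gene` and `protein_change` columns;
* the ANNOVAR exonic variant-function layout, keeping only lines classed
  `nonsynonymous SNV` (other classes are counted, not errors), and taking the
  first transcript annotation with a parsable `p.` token — transcripts can
  disagree on protein numbering and no input format says which is canonical,
  so "first parsable" is a documented choice, not a biological claim;
* a minimal VCF path for callers that can emit a `GENE|p.change` INFO value
  per ALT allele. We deliberately do not re-implement a consequence
  annotator: a VCF without such a key cannot be interpreted at the protein
  level and is counted as skipped.

Both compact (`L527I`) and HGVS (`p.Leu527Ile`) tokens are accepted
everywhere; the internal form is one-letter. Synonymous tokens are rejected
outright — a record that changes nothing is evidence of an upstream problem
worth surfacing, not data. Every parser maintains the conservation identity
*records + rejects + skipped = data lines*, so nothing is ever silently
dropped. Duplicate substitutions are collapsed with a warning: clustering
operates on residues, and a duplicate would only clutter the report.

## Structures and residue mapping

Coordinate files are parsed with bio3d. Multi-model (NMR) files contribute
their first model only; alternate locations resolve to the highest-occupancy
conformer; waters are dropped; non-amino-acid hetero groups are kept in a
separate table so they never participate in residue mapping but can
optionally join the pocket atom set. When several structures are available
for a protein, a frozen catalog of PDB cross-references is consulted and the
entry with the largest sequence span wins (ties break to the
lexicographically smallest identifier); "largest" could also have meant best
resolution, but span is what determines how many variants can be placed at
all, so span it is. A variant-level preferred structure always overrides.
Identifier fetches go through a cache directory, and an `offline` flag turns
a cache miss into an explicit error, so analyses are reproducible without
network access.

Author residue numbering — the numbers printed in the coordinate file — is
the matching convention. PDB entries are frequently offset from the UniProt
sequence by a constant, so a failed direct lookup triggers a constant-offset
scan over k in −30..30. An offset is accepted only when it is unique, the
variant's own wild type matches under it, and at least 80 % of all the
protein's variants match their wild types under the same k. The denominator
is all of the protein's variants, with out-of-chain positions counting as
non-matches: a lone variant that happens to land on a matching residue under
some stray shift must not manufacture a consensus of one. This heuristic is
a documented approximation of per-residue alignment (SIFTS-grade mapping is
out of scope); everything it decides is visible in the `offset_applied`
column. Mapped variants whose residue lacks a C-alpha atom are demoted to
`unmapped(no_calpha)` — the clustering distance is defined on C-alpha atoms
and a substitute atom would quietly change the metric.

## Spatial clustering

The pairwise metric is the Euclidean distance between the mutated residues'
C-alpha atoms, kept at full double precision internally and rounded to
0.1 Angstrom only at the report surface. Agglomeration is bottom-up average
linkage: the distance between two clusters is the unweighted arithmetic mean
of all cross-pair distances. The merge loop is written out explicitly (a
Lance–Williams size-weighted update) rather than delegated, because the
package promises bit-for-bit reproducible merge lists: at every step the
minimum-distance pair merges, and ties break deterministically to the
lexicographically smallest pair of smallest member labels. `stats::hclust`
with average linkage serves as an independent cross-check in the test suite,
alongside a brute-force oracle that recomputes every cross-pair mean from
the original matrix at each step; on this metric average linkage admits no
inversions, which the suite asserts over large batches of random instances.

Variants mapped to different chains cluster together — the distances are
geometric, and a homodimer's two copies of a residue are two distinct
labeled points (`Y370C (A)`, `Y370C (B)`).

A cut at a distance threshold turns the tree into a partition; multi-member
clusters are numbered 1..k (largest first), singletons are reported
separately with index 0. The default reporting threshold is 20 Angstrom:
variant clusters discussed in the cardiomyopathy literature sit at 9–19 Å
C-alpha distance, so 20 Å contains them all while excluding chain-scale
separations; no published cutoff exists, so the threshold is exposed on the
command line and printed prominently in the report. The cluster table's
height column reports the largest merge height inside each cluster — the
single number that says how tight the cluster is at its loosest joint.

## Pocket detection

Putative binding pockets are detected with a probe-sphere procedure in the
spirit of PASS (Putative Active Sites with Spheres): fill surface clefts
with probe spheres, keep the well-buried ones, and report each probe
cluster's weighted centroid as an active-site point.

* **Seeding.** Probes of radius 1.8 Å are placed tangent to every triplet of
  neighbouring heavy atoms (pair cutoff `2·max(vdW) + 2·r_probe`), by direct
  trilateration. Candidates clashing with any atom (tolerance 0.1 Å) or with
  a burial count below threshold are discarded.
* **Burial.** The burial count of a point is the number of protein heavy
  atoms within 8 Å (boundary inclusive). The retention threshold is 55
  atoms.
* **De-duplication.** Probe centers closer than 1.0 Å merge, keeping the more
  buried; among equals, the earlier candidate in canonical generation order
  wins. During accretion an existing probe always wins against a new
  near-duplicate — the existing set has already passed selection, and
  letting newcomers displace it would make layer boundaries order-sensitive.
* **Accretion.** New probes are placed tangent to two existing probes plus an
  atom, and to probe triplets, under the same filters, for at most 5 layers
  or until a layer adds nothing. Seeding alone cannot reach the middle of a
  wide cavity (a probe tangent to three wall atoms sits near the wall);
  accretion is what fills the interior.
* **Extraction.** Retained probes group by single linkage at 3.0 Å
  (delegated to `stats::hclust`); groups smaller than 3 probes are dropped;
  each pocket's center is the burial-weighted centroid of its probes and its
  weight the summed burial, ranking pockets descending.

All numeric parameters follow the published PASS defaults and are exposed
through `pocket_params()`. Hydrogens are ignored (deposited structures
rarely have them); van der Waals radii come from a shipped element table;
hetero atoms are excluded from the burial set by default so pockets are
found in apo structures, with a flag to include them. Because every step is
driven by pairwise geometry and a canonical atom ordering (chain, residue,
atom name), the procedure is deterministic and equivariant under rigid
motions — rotating the input rotates the pockets, to within floating-point
noise — and both properties are asserted in the tests. A variant whose
C-alpha lies within 8 Å of a pocket center (inclusive) is flagged as
pocket-proximal, with the distance reported.

The weighted centroid is our reading of "the center" of a probe cluster; the
original method's exact weighting for its active-site points is not
published in a reproducible form, and on the geometric fixtures the centroid
agrees with an independent dense-grid burial maximization to well under the
2 Å the tests demand.

## Pathogenicity annotation

Local snapshot files of HUMSAVAR (UniProt's curated missense catalogue) and
a ClinVar variant-summary table are parsed into lookup tables; nothing is
downloaded, and snapshot paths appear in the provenance because label sets
drift between releases. ClinVar rows are filtered to GRCh37 to match the
pipeline's hg19 coordinates. HUMSAVAR matches on the protein key (gene,
wild type, position, mutant); ClinVar matches on the genomic key
(chromosome, position, ref, alt) when the variant has coordinates, falling
back to the protein key — the genomic key is the more specific assertion,
so it takes precedence, a choice the report records by printing the match
key. Conflicting sources are both shown, never merged into a consensus: the
package reports evidence, it does not adjudicate it. Label normalization
(benign / pathogenic / uncertain / other) is data — a shipped, editable
mapping table — with a containment-rule fallback for unseen free-text
ClinVar labels.

## Stability prediction

Two predictors sit behind one interface. The external adapter runs any
stand-alone tool honouring a one-line contract (`"<sequence> <wt><pos><mut>"`
in, `"<direction> <ddg>"` out), with a per-variant timeout (default 120 s);
timeouts, crashes and garbled output degrade to `neutral` rows with notes,
never aborting the run, and a missing executable fails before the first
variant. A reported ddG overrides an inconsistent direction claim, with
|ddG| < 0.05 kcal/mol treated as neutral and negative values as
destabilizing.

The built-in baseline is deliberately transparent rather than accurate: a
score `s = −(0.2·|ΔH| + 0.01·|ΔV|)` from Kyte–Doolittle hydropathy and
residue-volume differences (shipped tables), calling `decrease` below −0.3
and `neutral` otherwise. It never predicts `increase` — a
magnitude-of-change score has no basis for calling a substitution
stabilizing. It is symmetric by construction (tested over all 380 ordered
substitutions) and every output row carries `method = "baseline-heuristic"`
so nobody mistakes it for a trained predictor. Stability prediction is
opt-in: it is the most expensive optional stage when an external tool is
configured.

## Reporting

`run_pipeline()` orchestrates the stages; only variant parsing and structure
loading are hard failures, every optional stage degrades to a warning
section. Outputs are `report.html` (summary, per-variant table, cluster
table, pocket table, provenance), `variants.tsv` / `clusters.tsv` /
`pockets.tsv`, `run.json` (machine-readable provenance), a flagged PDB copy
in which each mutated residue's atoms carry its cluster index as B-factor
(singletons 0), and a PyMOL-syntax viewer script reproducing the cluster
colouring — interactive visualization is delegated to external viewers
rather than embedded. All writers are deterministic given the injected
timestamp, so identical inputs give byte-identical outputs; the tests assert
this end to end. Missing annotations render as `n/a`, mirroring the reality
that most cohort variants have no database entry. The `structvar` script in
the package's `exec/` directory is a thin command-line wrapper over
`pipeline_config()` + `run_pipeline()` with a `fixtures` subcommand for
regenerating test inputs.

## What the synthetic fixtures do and do not show

The generators produce: ideal helix C-alpha traces (rise 1.5 Å, 100° twist,
ring radius 2.3 Å — consecutive C-alphas `r round(helix_ca_spacing(), 3)` Å
apart, in closed form), with controllable sequence and numbering offset;
Fibonacci-sphere cavity shells whose interior center is known exactly;
two-cavity and convex (tetrahedral) variants; and toy variant tables and
database snippets. They are written as genuine PDB files because format
handling is the dominant failure mode in this domain, and every generator is
byte-deterministic.

These fixtures validate geometry, bookkeeping and determinism. They do not
resemble real proteins: no side chains, no packing irregularities, no
partially resolved loops, no real cavity roughness. A passing suite
therefore demonstrates that the algorithms do what their definitions say on
known geometry — not that the default pocket thresholds are well calibrated
for every deposited structure, nor that a 20 Å cluster threshold is
biologically meaningful for a particular protein. Problem sizes in the test
suite (shells of 60–92 atoms, helices of 10–20 residues, up to 1,000 random
clustering instances of n ≤ 12) were chosen to exercise every code path
while keeping the full suite fast enough to run on every change.

## Known limitations

* Offset recovery assumes one constant offset per chain; insertions within
  the mapped region defeat it (by design — such cases need real alignment).
* The minimal VCF path requires pre-annotated protein changes.
* The baseline stability heuristic is directional triage only; ddG
  magnitudes require an external predictor.
* Homology modelling for proteins without deposited structures is out of
  scope; the pipeline stops with an explicit "no structure" error.
* Pocket detection reports geometry (buried volume), not druggability or
  conservation; ranking is by burial weight alone.
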