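---
title: "Annotating plant NLR immune receptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating plant NLR immune receptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrscan)
```

## The problem

Nucleotide-binding leucine-rich-repeat proteins (NLRs) are the largest family
of intracellular immune receptors in plants. A canonical NLR strings together
an N-terminal signalling domain — a coiled-coil (CC), an RPW8-like domain, or
a Toll/interleukin-1-receptor-like domain (TIR) — a central NB-ARC
nucleotide-binding domain, and a C-terminal leucine-rich-repeat (LRR) region;
some TNLs additionally carry a post-LRR C-JID domain, and many
resistosome-forming CNLs begin with the short MADA motif. `nlrscan` identifies
these receptors in a protein FASTA, reconstructs each protein's domain
architecture, and assigns the standard classes CNL, RNL, TNL and NL, or the
partial classes CN, RN, TN and N when the N-terminal domain and/or the LRR is
missing.

## The annotation model

The engine works from two independent evidence layers.

**Domain evidence.** Per-domain profile-HMM hits for six models (CC, RPW8,
two TIR profiles collapsing to one type, NB-ARC, C-JID, MADA) are obtained
either from a live `hmmsearch` or from a precomputed tabular hit file.
Envelope coordinates define hit spans, because envelopes capture the full
extent of a match better than the aligned core. Hits of the same type on the
same protein are merged whenever they overlap or lie within
`merge_distance = 100` residues of one another: profile matches to the NB-ARC
in particular tend to arrive split in two or three pieces, and without merging
a single receptor would read as a tandem architecture. Merged domains of one
type are therefore always separated by more than 100 residues, and a genuine
tandem NLR fusion still yields two NB-ARC letters.

**Motif evidence.** Seventeen short motifs are screened with a pluggable
predictor: the extended-EDVID CC motif, six TIR structural motifs (bA, aA,
bC, aC, bDaD1, aD3), the nine conserved NB-ARC motifs (VG, P-loop, RNSB-A,
Walker-B, RNSB-B, RNSB-C, RNSB-D, GLPL, MHD) and the LxxLxL repeat motif of
the LRR. The count of *distinct* NB-ARC motif classes (0–9) is reported as an
indicator of NB-ARC integrity.

Decision rules, in pipeline order:

1. Domain hits are kept at independent E-value ≤ `evalue_cutoff` (default
   1e-5). MADA is exempt from this filter because weak MADA matches are
   informative: a MADA hit with bit score strictly greater than
   `mada_score_threshold = 20` is a genuine MADA, anything lower is reported
   as MADA-like.
2. Proteins are initially classed CN, RN, TN or N according to whether a CC,
   RPW8 or TIR domain starts before the first NB-ARC domain. Proteins without
   any NB-ARC evidence are discarded here — unless ultra mode retains them.
3. Only proteins still in class N are re-examined with motif evidence:
   upstream (pre-NB-ARC) CC motifs move them to CN, upstream TIR motifs to
   TN. Motif searches are more promiscuous than domain searches, so motif
   evidence is never allowed to override an unambiguous domain-based class,
   and a tie between upstream CC and TIR motif counts leaves the protein in
   class N.
4. LRR domains are assembled from chains of LxxLxL motifs scanned left to
   right: a start-to-start gap below `lrr_max_gap = 75` extends the chain, a
   gap of 75 or more is read as a break in the repeat region and the chain
   restarts there. Each chain needs at least `lrr_min_motifs = 4` motifs to
   become an LRR domain; with fewer than 4 motifs in the whole sequence the
   step is skipped entirely.
5. All domains are sorted by start position and emit one letter each
   (CC → C, RPW8 → R, TIR → T, NB-ARC → N, LRR → L, C-JID → j) to form the
   *domain string*, e.g. `TNLj`; a genuine N-terminal MADA prefixes `m`, as
   in `mCNL`. The string is searched for the substrings CNL, RNL, TNL, NL —
   in that priority, so a TNL is never mistaken for a bare NL — and the first
   match is the classification; otherwise the CN/RN/TN/N class carries
   forward. A *motif string* records the family letter of every motif hit in
   positional order (e.g. `CNNNLLLLLLLLLLL`); repeats are not collapsed.

**Ultra mode** disables the NB-ARC filter: every sequence with at least one
domain or motif hit is reported, with its motif string but no classification.
It exists for locus screening, where highly fragmented receptor relics (even
a single LRR motif) are of interest. The default-mode result set is by
construction a subset of the ultra-mode set on identical input.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `merge_distance` | 100 | aa | max gap between same-type hits that merges them (gap ≤ 100 merges) |
| `lrr_max_gap` | 75 | aa | start-to-start gap at which an LRR chain breaks (< 75 extends) |
| `lrr_min_motifs` | 4 | motifs | minimum chain size for an LRR domain |
| `mada_score_threshold` | 20 | bits | genuine MADA requires score strictly > 20 |
| `motif_threshold` | 0.8 | — | minimum predictor confidence for a motif hit |
| `evalue_cutoff` | 1e-5 | — | per-hit independent E-value cutoff (MADA exempt) |
| `mada_nterm_window` | 50 | aa | MADA start window for the `m` prefix |

The first four are the published rule set; their boundary semantics (≤ 100,
< 75, ≥ 4, > 20) are pinned by tests on both sides of each boundary. The
E-value cutoff is this package's choice of a conventional reporting
threshold. The `m` prefix window is our own: MADA is by definition
N-terminal, and 50 aa comfortably covers the motif's natural position while
excluding genuine-scoring matches that sit mid-protein; it is configurable.

## Gap conventions and coordinates

Coordinates are 1-based inclusive throughout (the R/Bioconductor convention),
including all output tables; HMMER's 1-based envelope coordinates are used
unchanged. A "gap" between two domains is the number of residues strictly
between them (`next_start − current_end − 1`). LRR inter-motif gaps are
measured start-to-start, which keeps the chaining rule independent of the
motif window width.

## The default motif predictor

The motif screen is a contract: any scorer that returns scored candidate
occurrences per motif class can be plugged in. The default is a deliberately
simple, fully deterministic position-specific scoring matrix (PSSM): for each
class a log-odds matrix (pseudocount 0.5, uniform background) is estimated
from a bundled seed alignment, each sequence window is scored, and the raw
score *s* is mapped to a confidence by `plogis((s − smax/2)/(smax/12))`,
where *smax* is the maximum attainable score. The consensus therefore scores
≈ 0.998 and random background ≈ 0; hits are reported at confidence ≥ 0.8
after per-class greedy suppression of overlapping windows (best score first,
leftmost on ties). The bundled seed alignments are **synthetic** — authored
variants around literature-style consensus sequences, shipped in
`inst/extdata/motif_seeds_synthetic/` — so the default predictor is a clean,
reproducible baseline, not a reimplementation of any trained classifier's
weights. Real-data sensitivity for divergent motifs will be lower than a
trained predictor's; for that use case, supply precomputed motif tables from
an external tool via `--motifs-tsv` or implement the predictor contract.

One naming note: the LRR motif is registered under its common name `LxxLxL`;
the pattern itself is a property of the seed alignment, not of the name.

## Profile search pathway

`search_domains()` shells out to `hmmsearch` (HMMER3) and parses the
per-domain table. The package bundles no curated profile databases; instead
`build_synthetic_profiles()` compiles small synthetic per-domain models with
`hmmbuild` at run time (deterministic, seeded) so the complete search
pathway is exercisable offline, and `scripts/fetch_pfam.sh` is the separate,
optional setup script that downloads the real curated models for production
use. Precomputed hit tables (`--domains-tsv`, either HMMER `--domtblout`
format or this package's own domain TSV) bypass the search entirely and are
the recommended route for reproducible pipelines.

## What the synthetic fixtures emulate — and what they do not

`generate_suite()` plants known architectures: all eight default-mode
classes, genuine/MADA-like/absent MADA, C-JID presence, gap boundaries at
74/75/76 and 99/100/101 residues, motif-based reclassification cases
(including the deliberate tie), tandem NB-ARC fusions and NB-ARC-less
fragments visible only in ultra mode. Ground truth is produced by
`evaluate_ground_truth()`, a plain loop-based restatement of the rules
written independently of the annotation engine, so agreement between the two
is a meaningful check of the engine rather than a tautology. Fixture
residues are uniform random background with exact motif consensus strings
planted — uniform rather than proteome-like composition, which maximises the
power of negative controls for the motif scorer. The fixtures do **not**
emulate real sequence divergence, compositional bias, integrated decoy
domains or split/merged gene models; passing the suite demonstrates that the
decision rules are implemented exactly, not that the statistical search
layers reach any particular sensitivity on real proteomes.

Problem sizes used by the shipped checks: 200-fixture suites for end-to-end
agreement, 1000 random instances per oracle-equivalence property (interval
merging against a brute-force transitive-closure union; LRR chaining against
exhaustive chain enumeration), and single-protein live `hmmsearch` runs
against the synthetic models.

## Numerical and degenerate-input choices

* Merging at gap exactly 100 merges; LRR chaining at gap exactly 75 breaks;
  MADA at score exactly 20 is MADA-like. All three boundaries are tested on
  both sides.
* Ties in motif-based reclassification keep class N (promiscuous evidence
  must not flip a class).
* Empty inputs are not errors: an empty FASTA record set yields empty outputs
  and exit 0; an empty motif set yields empty strings and count 0.
* Duplicate FASTA ids, hits referencing unknown ids, and hits extending past
  the sequence end are hard errors naming the offending identifiers.
* Unknown residues (X and friends) score 0 (background-neutral) in the PSSM.
* `threads` only re-chunks the motif scan; outputs are byte-identical for
  any thread count, and the scan result is invariant to chunking by
  construction (tested 1 vs 8 chunks).

## Known limitations

* No detection of non-canonical integrated domains (decoys) and no
  CC-subclass (G10/RPW8-like vs Rx-like) discrimination beyond the RPW8
  model.
* The motif screen has no RPW8-family motifs, so motif-based
  reclassification can produce CN or TN but never RN — matching the motif
  set it models.
* Nucleotide input and six-frame translation are out of scope; inputs are
  protein sequences.
* With tandem NB-ARC fusions the substring classifier reports the first
  matching class (e.g. `CNLNL` → CNL); the duplicated NB-ARC remains visible
  in the domain table and the `n_nbarc_domains` column.
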