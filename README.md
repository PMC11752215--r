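# nlrscan

Identification and classification of plant NLR immune receptors from protein
sequences.

Nucleotide-binding leucine-rich-repeat proteins (NLRs) are intracellular
immune receptors that dominate plant disease-resistance genetics. `nlrscan`
takes a protein FASTA (a whole proteome or a single locus), detects the
NLR-associated domains and short motifs, reconstructs each protein's
architecture, and classifies it — for breeders, pathologists and genome
annotators who need reproducible NLR inventories.

## Method

Two evidence layers feed one rule engine:

* **Domains** — per-domain profile-HMM hits for six models (CC/Rx-type
  coiled-coil, RPW8, TIR ×2 profiles, NB-ARC, C-JID, MADA), from a live
  HMMER `hmmsearch` or a precomputed hit table. Same-type hits that overlap
  or lie within 100 aa are merged (split NB-ARC matches are common). A MADA
  hit is genuine at bit score > 20, otherwise MADA-like.
* **Motifs** — 17 short motifs (extended-EDVID; six TIR motifs; the nine
  conserved NB-ARC motifs VG, P-loop, RNSB-A, Walker-B, RNSB-B/C/D, GLPL,
  MHD; the LxxLxL repeat) screened by a deterministic PSSM predictor behind
  a pluggable contract.

Proteins without NB-ARC evidence are discarded (unless `--ultra`); the rest
are classed CN/RN/TN/N by the domain upstream of the first NB-ARC, class-N
proteins are rescued by upstream CC/TIR *motifs*, and LRR domains are built
from chains of ≥ 4 LxxLxL motifs with start-to-start gaps < 75 aa (a larger
gap restarts the chain). Sorted domains then spell a **domain string**
(CC → C, RPW8 → R, TIR → T, NB-ARC → N, LRR → L, C-JID → j, genuine
N-terminal MADA → `m` prefix), which is searched for CNL > RNL > TNL > NL to
give the classification; a **motif string** records every motif hit in order
(e.g. `CNNNLLLLLLLLLLL`), and the count of distinct NB-ARC motif classes
(0–9) reports NB-ARC integrity.

## Worked example

Annotate a protein from precomputed hit tables (the same works with a live
search by omitting `--domains-tsv`/`--motifs-tsv`):

```r
library(nlrscan)

# a synthetic MADA-CC-NBARC-LRR receptor with known ground truth
reg <- motif_classes(); nb <- reg$name[reg$family == "NBARC"]
elements <- c(
  list(list(kind = "domain", dtype = "MADA",  start = 2,   end = 18,  score = 30, evalue = 0.5)),
  list(list(kind = "domain", dtype = "CC",    start = 30,  end = 124, score = 40, evalue = 1e-15)),
  list(list(kind = "domain", dtype = "NBARC", start = 220, end = 499, score = 80, evalue = 1e-40)),
  lapply(seq_along(nb), function(k) list(kind = "motif", class = nb[k],     position = 230 + (k - 1) * 30)),
  lapply(0:7,           function(k) list(kind = "motif", class = "LxxLxL",  position = 540 + k * 25))
)
fx <- generate_fixture(architecture_spec("example_nlr", elements, seed = 17))
write_fasta(fx$record, "example.fasta")
write_domain_table(fx$domain_hits, "example_domains.tsv")
write_motif_table(fx$motif_hits, "example_motifs.tsv")

run_pipeline("example.fasta", "example_out",
             domains_tsv = "example_domains.tsv",
             motifs_tsv = "example_motifs.tsv")
```

`example_out/results.tsv`:

```
sequence_id	length	classification	domain_string	motif_string	nbarc_motif_count	mada_status	cjid_status
example_nlr	756	CNL	mCNL	NNNNNNNNNLLLLLLLL	9	MADA	no
```

Read: the protein is a canonical **CNL** whose architecture reads
`mCNL` — a genuine N-terminal MADA motif, a coiled-coil, one NB-ARC and one
LRR domain; all **9** conserved NB-ARC motifs are present (an intact
nucleotide-binding domain), the motif string shows the nine NB-ARC motifs
followed by the eight LxxLxL repeats, and no C-JID. `example_out/` also holds
`domains.tsv` and `motifs.tsv` (every merged domain and motif hit, 1-based
inclusive coordinates), `nlrs.fasta` (full sequences of reported NLRs),
`nbarc.fasta` (extracted NB-ARC domain sequences) and `run_log.txt`.

The same run from a shell:

```sh
Rscript inst/scripts/nlrscan -i example.fasta -o example_out \
    --domains-tsv example_domains.tsv --motifs-tsv example_motifs.tsv
```

Useful flags: `--ultra` (keep NB-ARC-less fragments, reported with a motif
string and no classification), `--lrr-gap`, `--lrr-min-motifs`,
`--merge-distance`, `--mada-threshold`, `--motif-threshold`, `--evalue`,
`--threads`, `--force`.

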