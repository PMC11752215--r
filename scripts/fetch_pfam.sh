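#!/usr/bin/env bash
# OPTIONAL setup: download the real curated profile HMMs (network required).
# The package never needs these for its tests; they enable realistic searches.
#   usage: scripts/fetch_pfam.sh <output_dir>
set -euo pipefail
out="${1:?usage: fetch_pfam.sh <output_dir>}"
mkdir -p "$out"
base="https://www.ebi.ac.uk/interpro/wwwapi/entry/pfam"
for acc in PF00931 PF01582 PF13676 PF05659 PF18052 PF20160; do
  curl -sSfL "$base/$acc?annotation=hmm" | gunzip -c > "$out/$acc.hmm"
  echo "fetched $acc"
done
curl -sSfL "https://cdn.elifesciences.org/articles/49956/elife-49956-supp2-v2.hmm" \
  > "$out/MADA.hmm"
echo "fetched MADA"
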