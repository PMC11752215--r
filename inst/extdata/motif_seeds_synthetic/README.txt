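Synthetic seed alignments, one aligned-FASTA file per NLR-associated motif
class. These are authored variants around a literature-style consensus for
each motif (10 sequences each); they are NOT curated training alignments.
They parameterise the deterministic default motif predictor
(default_predictor()).
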