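baa952808865f5272a9c56b328784ff6  example_positives.fasta
e9254d046d2b3eb97c1b0656dd4c5f18  example_negatives.fasta
afe14cabb9f7425a4645a71b5c52c1c1  example_candidates.fasta
f8043d191f9c0d6e7dcd8257ef1b3206  example_hits.tsv
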