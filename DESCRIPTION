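Package: rippnet
Title: Neural Network Classification of RiPP Precursor Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Class-independent identification of ribosomally synthesized and
    post-translationally modified peptide (RiPP) precursor peptides from
    short amino-acid sequences. Peptides of 20-120 residues are one-hot
    encoded into fixed 20 x 120 matrices and scored by one of five neural
    architectures (a bidirectional LSTM, linear and parallel convolutional
    networks, and CNN+LSTM hybrids) trained with an imbalance-aware loop
    that periodically resamples the negative class and checkpoints the
    best-accuracy weights. Ships FASTA-in/TSV-out training and
    classification front ends, an HMM-hit enrichment report, and a
    synthetic motif-peptide generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
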