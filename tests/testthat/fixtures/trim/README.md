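# Trimmer oracle fixtures (synthetic)

Twelve seeded toy alignments (`case_NN.fasta`) with the column sets kept
under the relaxed trimming settings (`case_NN.kept.txt`, space-separated
1-based original column indices).

These are **synthetic reference outputs**: the expected column sets were
produced once by the independent, loop-based reference transcription of the
published conserved-block selection procedure in
`../..//helper-oracle-trim.R` (not by the original external trimming
binary, which is not redistributable here), and frozen by
`scripts/make-trim-fixtures.R`. The test suite checks the package
implementation against both the frozen files and a fresh run of the
reference.
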