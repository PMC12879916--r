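# Observed deconvoluted monoisotopic masses (Da), one per line, for the
# synthetic SELENOW analogue digest. Six of the seven tryptic peptides
# are present (the 10-residue peptide spanning residues 28-37 is not),
# so the union of matched peptides covers 75 of 85 residues (88.24%).
# The Sec-containing peptide appears as its carbamidomethylated
# dehydroalanine form (Se lost during sample preparation).
1189.60127
1725.74168
1732.79914
843.47018
1638.78895
1095.51965
# an unrelated mass that matches nothing within 20 ppm
1500.00000
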