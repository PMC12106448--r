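# Conservative fragments identifying probiotic preparations among free-text
# drug names (normalized: uppercase, punctuation stripped).
PROBIOTIC
LACTOBACILLUS
BIFIDOBACTERIUM
SACCHAROMYCES BOULARDII
ACIDOPHILUS
BACILLUS COAGULANS
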