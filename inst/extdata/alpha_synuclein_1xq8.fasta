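>alpha_synuclein_human_140 micelle-bound alpha-synuclein sequence (PDB 1XQ8)
MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVH
GVATVAEKTKEQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQL
GKNEEGAPQEGILEDMPVDPDNEAYEMPSEEGYQDYEPEA
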