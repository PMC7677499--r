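# Default per-element van der Waals radii (Angstrom).
# Elements not listed fall back to 1.80 A.
H  1.20
C  1.70
N  1.50
O  1.40
S  1.85
P  1.90
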