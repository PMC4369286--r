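# McGowan atomic volume contributions (cm3/mol), literature constants
# of the McGowan characteristic-volume method as tabulated by Abraham
# and McGowan. V = [sum(atoms) - 6.56 * bonds] / 100 with
# bonds = atoms - 1 + rings.
element,volume_cm3_per_mol
C,16.35
H,8.71
O,12.43
N,14.39
F,10.48
Cl,20.95
Br,26.21
I,34.53
S,22.91
P,24.87
Si,26.83
B,18.32
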