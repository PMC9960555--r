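# PFSA mass-calibration reference ions (repo defaults, user-editable).
# The calibration mixture contains perfluorobutane- (C4), perfluorohexane-
# (C6) and perfluorooctane (C8) sulfonic acid. Negative mode uses the three
# [M-H]- monomers plus proton-bound dimers to span roughly m/z 299-1037;
# the positive-mode series ([M+2K-H]+ and a dimer analogue, spanning roughly
# m/z 377-1115) is a package convention chosen to be consistent with
# KCl-salted extracts -- vendor software does not document its positive-mode
# reference species. Species labels are formula deltas on the base formula,
# so dimers are written as M+<partner formula>.
# Columns: label, polarity, formula, species.
label	polarity	formula	species
PFBS [M-H]-	negative	C4HF9O3S	M-H
PFHxS [M-H]-	negative	C6HF13O3S	M-H
PFOS [M-H]-	negative	C8HF17O3S	M-H
PFHxS/PFOS [2M-H]-	negative	C6HF13O3S	M+C8HF17O3S-H
PFOS [2M-H]-	negative	C8HF17O3S	M+C8HF17O3S-H
PFBS [M+2K-H]+	positive	C4HF9O3S	M+K2-H
PFHxS [M+2K-H]+	positive	C6HF13O3S	M+K2-H
PFOS [M+2K-H]+	positive	C8HF17O3S	M+K2-H
PFOS [2M+2K-H]+	positive	C8HF17O3S	M+C8HF17O3S+K2-H
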