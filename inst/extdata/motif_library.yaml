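# Default peptide family motif library.
# Dialect: x = any residue, [..] = class, {n} = repetition,
# trailing $am = amidation required, leading ^ = N-terminal anchor;
# unanchored patterns match a C-terminal suffix.
# The last three patterns are provisional (transcribed from family
# names only).
APGWamide: "xPGW$am"
FMRFamide: "F[MIL]RF$am"
LFRFamide: "LFRF$am"
FxRIamide: "xSSFxRI"
myomodulin: "x[ML]LRL$am"
PXVFamide: "Px[IV]F$am"
sCAP_pyrokinin: "FxPRM$am"
luqin: "QGRF$am"
PFGx8amide: "PFGx{8}$am"
RxIamide: "RxI$am"
Wx3Yamide: "Wx{3}Y$am"
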