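name	sequence	description
CutO_MRS	MDHGAMDHSATPMQGMDGMADMMSLPGMAEMHAAMEGGLSM	methionine-rich segment between cupredoxin domains 1 and 2 of CutO, removed in the dMRS variant
CutF_Cterm	PEPEGPPPRL	C-terminal proline-rich segment of CutF (residues 109-118), removed in the dC-ter variant
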