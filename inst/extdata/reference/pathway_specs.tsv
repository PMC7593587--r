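key	display_name	ref_id	min_identity	min_coverage	expects_codon	expects_residue	recoded_index	verdict_component	query_only
pylB	3-methylornithine synthase (PylB)	ref_pylB_synthetic	35	70	NA	NA	NA	TRUE	FALSE
pylC	3-methylornithine-L-lysine ligase (PylC)	ref_pylC_synthetic	35	70	NA	NA	NA	TRUE	FALSE
pylD	3-methylornithyl-N6-L-lysine dehydrogenase (PylD)	ref_pylD_synthetic	35	70	NA	NA	NA	TRUE	FALSE
pylS_N	pyrrolysyl-tRNA synthetase, N-terminal gene (PylSn)	ref_pylS_N_synthetic	35	70	NA	NA	NA	TRUE	FALSE
pylS_C	pyrrolysyl-tRNA synthetase, C-terminal gene (PylSc)	ref_pylS_C_synthetic	35	70	NA	NA	NA	TRUE	FALSE
mttB	trimethylamine methyltransferase (MttB, Pyl-containing)	ref_mttB_synthetic	35	70	TAG	O	200	TRUE	FALSE
ramA	methylamine methyltransferase corrinoid reductive activase (RamA)	ref_ramA_synthetic	35	70	NA	NA	NA	FALSE	FALSE
mttC	TMA methyltransferase cognate corrinoid protein (MttC)	ref_mttC_synthetic	35	70	NA	NA	NA	FALSE	FALSE
cutC	choline trimethylamine lyase (CutC)	ref_cutC_synthetic	35	70	NA	NA	NA	FALSE	FALSE
cutD	choline trimethylamine lyase activating enzyme (CutD)	ref_cutD_synthetic	35	70	NA	NA	NA	FALSE	FALSE
grdA_like	glycine betaine reductase selenoprotein (GrdA-like, Sec-containing)	ref_grdA_like_synthetic	35	70	TGA	U	80	FALSE	FALSE
selA	L-seryl-tRNA(Sec) selenium transferase (SelA)	ref_selA_synthetic	35	70	NA	NA	NA	FALSE	FALSE
selB	selenocysteine-specific elongation factor (SelB)	ref_selB_synthetic	35	70	NA	NA	NA	FALSE	FALSE
selD	selenide, water dikinase (SelD)	ref_selD_synthetic	35	70	NA	NA	NA	FALSE	FALSE
bcct	betaine/carnitine/choline transporter (BCCT family)	ref_bcct_synthetic	35	70	NA	NA	NA	FALSE	FALSE
mtbB	dimethylamine methyltransferase (MtbB; absence query)	ref_mtbB_synthetic	35	70	NA	NA	NA	FALSE	TRUE
mtmB_like	monomethylamine methyltransferase-like (MtmB-like decoy, no TAG)	ref_mtmB_like_synthetic	35	70	NA	NA	NA	FALSE	TRUE
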