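# Published benchmark of the consensus protocol on 18,874 single-location
# reviewed metazoan proteins: confusion counts per rule/category together
# with the printed sensitivity (%), specificity (%) and MCC.
# Panels: mitochondria (1870 positives / 17004 negatives, TargetP and
# WoLF PSORT rules), secreted (5724 / 13150, cumulative vote tiers),
# location (one-vs-rest over all 18,874 for the WoLF PSORT categories).
panel	rule	tp	fp	tn	fn	sn	sp	mcc
mitochondria	TargetP	930	972	16032	940	49.7	94.3	0.44
mitochondria	WoLFPSORT	920	482	16522	950	49.2	97.2	0.53
mitochondria	TargetP AND WoLFPSORT	794	262	16742	1076	42.5	98.5	0.53
mitochondria	TargetP OR WoLFPSORT	1056	1202	15802	814	56.5	92.9	0.45
secreted	S	5024	276	12874	700	87.8	97.9	0.88
secreted	S+HLS	5350	522	12628	374	93.5	96.0	0.89
secreted	S+HLS+LS	5413	794	12356	311	94.6	94.0	0.87
secreted	S+HLS+LS+WLS	5440	1462	11688	284	95.0	88.9	0.80
location	Cytoplasm	1095	1124	15779	876	55.6	93.4	0.46
location	Cytoskeleton	218	63	18020	573	27.6	99.7	0.45
location	ER	257	187	17906	524	32.9	99.0	0.42
location	Golgi	12	21	18584	257	4.5	99.9	0.12
location	Lysosome	1	8	18675	190	0.5	100.0	0.02
location	Nucleus	2979	893	14190	812	78.6	94.1	0.72
location	Peroxisome	4	101	18653	116	3.3	99.5	0.03
location	Plasma membrane	2767	647	14880	580	82.7	95.8	0.78
location	Vacuole	0	0	18855	19	0.0	100.0	NA
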