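gene_id	MB231_s1	MB231_s2	Hs578T_s1	MCF10A_s1
ANLN	-3.275	-2.657	-2.139	-2.230
CHEK1	-2.766	-2.441	-4.719	-0.218
KIF11	-2.475	-2.231	-3.832	-2.770
RRM1	-2.637	-2.347	-2.053	-0.955
RRM2	-3.647	-2.915	-2.518	-1.348
TPX2	-1.932	-1.697	-3.864	-1.452
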