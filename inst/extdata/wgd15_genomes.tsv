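# Summary statistics for 15 WGD-descendant genomes from a published survey
# of 6 ancient whole-genome duplications.  Columns: t_mya = approximate time
# since the WGD (My); n = total genes; m = single-copy genes; one_minus_theta
# = published proportion of ancestral loci reduced to single copy; u_bar =
# observed mean length of two-sided single-copy runs (analytical units with
# u >= 1).  The rearrangement distance d is not published and is left NA.
genome	wgd_event	t_mya	n	m	one_minus_theta	u_bar	d
S. cerevisiae	yeast	150	5616	4498	0.89	6.0958	NA
C. glabrata	yeast	150	5180	4382	0.92	5.3839	NA
V. polyspora	yeast	150	5112	4164	0.9	4.922	NA
S. bayanus	yeast	150	5857	4773	0.9	5.8297	NA
N. castelli	yeast	150	5213	4053	0.88	5.0717	NA
Paramecium	paramecium	20	38626	14576	0.55	2.0299	NA
populus	populus	70	20082	7228	0.53	1.6402	NA
Arabidopsis	arabidopsis	50	25655	13267	0.68	3.6086	NA
fugu	teleost	350	14251	12653	0.941	3.806	NA
medaka	teleost	350	14564	13352	0.957	5.0629	NA
stickleback	teleost	350	16726	14876	0.941	4.3792	NA
tetraodon	teleost	350	17120	16088	0.969	6.876	NA
chicken	amniote	450	10077	8495	0.915	3.6122	NA
opossum	amniote	450	13339	11589	0.93	5.5507	NA
human	amniote	450	13828	12144	0.935	3.818	NA
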