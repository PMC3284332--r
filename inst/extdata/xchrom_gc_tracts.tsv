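progeny_id	distal_flank_pos	first_converted_pos	n_converted	last_converted_pos	donor_parent	proximal_flank_pos	min_tract	max_tract	band	location	gene
1e	6633119	6633448	4	6633592	P2	6633865	144	746	6C10	intron_exon	CG3168
3c	9157653	9159700	3	9159935	P1	9161089	235	3436	8D4	intron_exon	CG32703
3d	10914005	10914112	15	10914724	P1	10916406	612	2401	10A2	intron	CG42339
2b	15151729	15151810	3	15151997	P1	15152643	187	914	13B4	intergenic	NA
3c	19520853	19521068	3	19521155	P1	19521507	87	654	18D8	intergenic	NA
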