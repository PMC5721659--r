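accession	taxon	family	order	full_bp	gc_percent	lsc_bp	ssc_bp	ir_bp	coding_bp	coding_gc_percent	noncoding_bp	noncoding_gc_percent
MG524995	Nyssa wenshanensis	Nyssaceae	Cornales	156598	37.9	86109	18261	26114	91073	40.3	65525	34.6
MG525000	Nyssa sinensis	Nyssaceae	Cornales	156567	37.9	86089	18250	26114	91073	40.3	65494	34.6
MG525005	Camptotheca acuminata	Nyssaceae	Cornales	157811	37.8	87333	18760	25859	91078	40.3	66772	34.4
MG525002	Davidia involucrata	Davidiaceae	Cornales	158131	37.8	87335	18856	25970	91037	40.3	67094	34.4
MG525001	Mastixia caudatilimba	Mastixiaceae	Cornales	158221	37.8	87418	18797	26003	90962	40.3	67259	34.4
MG524991	Diplopanax stachyanthus	Mastixiaceae	Cornales	158715	37.8	87679	18632	26202	90944	40.2	67771	34.6
MG524994	Hydrangea heteromalla	Hydrangeaceae	Cornales	157889	37.8	86907	18738	26122	91138	40.1	66751	34.7
MG524992	Hydrangea aspera	Hydrangeaceae	Cornales	157637	37.8	86815	18646	26088	91189	40.2	66448	34.5
MG524993	Deutzia crassifolia	Hydrangeaceae	Cornales	157035	37.6	86583	18714	25869	91099	40.1	65936	34.1
MG525003	Alangium alpinum	Alangiaceae	Cornales	156673	37.7	86181	18592	25950	90842	40.2	65831	34.2
MG524996	Alangium chinense	Alangiaceae	Cornales	156684	37.7	86185	18603	25948	90824	40.2	65860	34.2
MG524990	Cornus capitata 1	Cornaceae	Cornales	157200	38.2	86564	18412	26112	90928	40.5	66272	35.0
MG524998	Cornus capitata 2	Cornaceae	Cornales	157200	38.2	86564	18412	26112	90928	40.5	66272	35.0
MG525004	Cornus controversa	Cornaceae	Cornales	158668	37.8	87835	18705	26064	90823	40.4	67845	34.3
MG524999	Curtisia dentata	Curtisiaceae	Cornales	158548	37.7	87158	18490	26450	91018	40.2	67530	34.3
MG524997	Fouquieria diguetii	Fouquieriaceae	Ericales	157895	37.3	87321	18482	26046	91244	39.9	66651	33.7
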