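##fileformat=VCFv4.2
##source=hapcompare
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	synthetic_toolB
chr10	595	.	A	T	.	PASS	.	GT:PS	1|0:595
chr10	1462	.	A	T	.	PASS	.	GT:PS	1|0:595
chr10	1902	.	A	T	.	PASS	.	GT:PS	0|1:595
chr10	2487	.	A	T	.	PASS	.	GT:PS	0|1:595
chr10	3227	.	A	T	.	PASS	.	GT:PS	0|1:3227
chr10	3414	.	A	T	.	PASS	.	GT:PS	0|1:3227
chr10	9561	.	A	T	.	PASS	.	GT:PS	1|0:3227
chr10	11254	.	A	T	.	PASS	.	GT:PS	0|1:11254
chr10	11618	.	A	T	.	PASS	.	GT:PS	0|1:11254
chr10	11879	.	A	T	.	PASS	.	GT:PS	0|1:11879
chr10	13078	.	A	T	.	PASS	.	GT:PS	1|0:11879
chr10	15889	.	A	T	.	PASS	.	GT:PS	0|1:11879
chr10	19201	.	A	T	.	PASS	.	GT:PS	1|0:11879
chr10	21242	.	A	T	.	PASS	.	GT:PS	0|1:11879
chr10	22095	.	A	T	.	PASS	.	GT:PS	0|1:22095
chr10	22479	.	A	T	.	PASS	.	GT:PS	0|1:22095
chr10	24268	.	A	T	.	PASS	.	GT:PS	1|0:22095
chr10	25132	.	A	T	.	PASS	.	GT:PS	0|1:25132
chr10	27781	.	A	T	.	PASS	.	GT:PS	1|0:25132
chr10	29477	.	A	T	.	PASS	.	GT:PS	0|1:29477
chr10	29818	.	A	T	.	PASS	.	GT:PS	1|0:29477
chr10	30615	.	A	T	.	PASS	.	GT:PS	1|0:30615
chr10	30643	.	A	T	.	PASS	.	GT:PS	0|1:30615
chr10	31073	.	A	T	.	PASS	.	GT:PS	0|1:31073
chr10	31194	.	A	T	.	PASS	.	GT:PS	0|1:31073
chr10	31244	.	A	T	.	PASS	.	GT:PS	1|0:31244
chr10	33110	.	A	T	.	PASS	.	GT:PS	0|1:31244
chr10	33339	.	A	T	.	PASS	.	GT:PS	1|0:31244
chr10	34567	.	A	T	.	PASS	.	GT:PS	0|1:31244
chr10	36175	.	A	T	.	PASS	.	GT:PS	0|1:36175
chr10	36418	.	A	T	.	PASS	.	GT:PS	0|1:36175
chr10	36901	.	A	T	.	PASS	.	GT:PS	1|0:36901
chr10	39099	.	A	T	.	PASS	.	GT:PS	0|1:36901
chr10	40045	.	A	T	.	PASS	.	GT:PS	1|0:36901
chr10	40204	.	A	T	.	PASS	.	GT:PS	0|1:36901
chr10	41884	.	A	T	.	PASS	.	GT:PS	1|0:36901
chr10	43223	.	A	T	.	PASS	.	GT:PS	1|0:36901
chr10	45525	.	A	T	.	PASS	.	GT:PS	1|0:45525
chr10	48275	.	A	T	.	PASS	.	GT:PS	1|0:45525
chr10	49432	.	A	T	.	PASS	.	GT:PS	0|1:49432
chr10	50315	.	A	T	.	PASS	.	GT:PS	0|1:49432
chr10	54217	.	A	T	.	PASS	.	GT:PS	1|0:49432
chr10	56304	.	A	T	.	PASS	.	GT:PS	0|1:56304
chr10	58618	.	A	T	.	PASS	.	GT:PS	1|0:58618
chr10	59144	.	A	T	.	PASS	.	GT:PS	0|1:58618
chr10	59167	.	A	T	.	PASS	.	GT:PS	1|0:58618
chr10	59784	.	A	T	.	PASS	.	GT:PS	1|0:59784
chr10	61019	.	A	T	.	PASS	.	GT:PS	0|1:59784
chr10	61800	.	A	T	.	PASS	.	GT:PS	0|1:61800
chr10	63143	.	A	T	.	PASS	.	GT:PS	0|1:63143
chr10	63966	.	A	T	.	PASS	.	GT:PS	0|1:63966
chr10	64659	.	A	T	.	PASS	.	GT:PS	0|1:63966
chr10	65051	.	A	T	.	PASS	.	GT:PS	0|1:65051
chr10	66451	.	A	T	.	PASS	.	GT:PS	./.:65051
chr10	67538	.	A	T	.	PASS	.	GT:PS	0|1:65051
chr10	69840	.	A	T	.	PASS	.	GT:PS	1|0:69840
chr10	71363	.	A	T	.	PASS	.	GT:PS	0|1:69840
chr10	72691	.	A	T	.	PASS	.	GT:PS	0|1:69840
chr10	73084	.	A	T	.	PASS	.	GT:PS	1|0:69840
chr10	73741	.	A	T	.	PASS	.	GT:PS	0|1:73741
chr10	77282	.	A	T	.	PASS	.	GT:PS	0|1:73741
chr10	77643	.	A	T	.	PASS	.	GT:PS	./.:73741
chr10	79776	.	A	T	.	PASS	.	GT:PS	0|1:79776
chr10	81763	.	A	T	.	PASS	.	GT:PS	1|0:79776
chr10	82273	.	A	T	.	PASS	.	GT:PS	0|1:79776
chr10	82614	.	A	T	.	PASS	.	GT:PS	1|0:79776
chr10	82697	.	A	T	.	PASS	.	GT:PS	1|0:79776
chr10	83107	.	A	T	.	PASS	.	GT:PS	0|1:83107
chr10	83257	.	A	T	.	PASS	.	GT:PS	0|1:83107
chr10	83972	.	A	T	.	PASS	.	GT:PS	1|0:83107
chr10	85012	.	A	T	.	PASS	.	GT:PS	0|1:85012
chr10	85195	.	A	T	.	PASS	.	GT:PS	1|0:85012
chr10	86117	.	A	T	.	PASS	.	GT:PS	1|0:85012
chr10	87812	.	A	T	.	PASS	.	GT:PS	0|1:87812
chr10	88177	.	A	T	.	PASS	.	GT:PS	1|0:87812
chr10	88736	.	A	T	.	PASS	.	GT:PS	1|0:88736
chr10	88934	.	A	T	.	PASS	.	GT:PS	1|0:88736
chr10	89214	.	A	T	.	PASS	.	GT:PS	1|0:88736
chr10	89276	.	A	T	.	PASS	.	GT:PS	0|1:88736
chr10	89387	.	A	T	.	PASS	.	GT:PS	1|0:89387
chr10	90396	.	A	T	.	PASS	.	GT:PS	1|0:89387
chr10	92840	.	A	T	.	PASS	.	GT:PS	./.:92840
chr10	92979	.	A	T	.	PASS	.	GT:PS	0|1:92979
chr10	92994	.	A	T	.	PASS	.	GT:PS	1|0:92979
chr10	93582	.	A	T	.	PASS	.	GT:PS	1|0:92979
chr10	94293	.	A	T	.	PASS	.	GT:PS	1|0:92979
chr10	94668	.	A	T	.	PASS	.	GT:PS	1|0:94668
chr10	94890	.	A	T	.	PASS	.	GT:PS	1|0:94668
chr10	95248	.	A	T	.	PASS	.	GT:PS	0|1:95248
chr10	95270	.	A	T	.	PASS	.	GT:PS	1|0:95248
chr10	95641	.	A	T	.	PASS	.	GT:PS	0|1:95248
chr10	98541	.	A	T	.	PASS	.	GT:PS	1|0:98541
chr10	100003	.	A	T	.	PASS	.	GT:PS	1|0:98541
chr10	100115	.	A	T	.	PASS	.	GT:PS	0|1:98541
chr10	101296	.	A	T	.	PASS	.	GT:PS	1|0:98541
chr10	102963	.	A	T	.	PASS	.	GT:PS	0|1:102963
chr10	103844	.	A	T	.	PASS	.	GT:PS	1|0:103844
chr10	104112	.	A	T	.	PASS	.	GT:PS	1|0:104112
chr10	104497	.	A	T	.	PASS	.	GT:PS	0|1:104112
chr10	104824	.	A	T	.	PASS	.	GT:PS	0|1:104824
chr10	106361	.	A	T	.	PASS	.	GT:PS	1|0:104824
chr10	106541	.	A	T	.	PASS	.	GT:PS	1|0:104824
chr10	107271	.	A	T	.	PASS	.	GT:PS	1|0:104824
chr10	108449	.	A	T	.	PASS	.	GT:PS	0|1:108449
chr10	109024	.	A	T	.	PASS	.	GT:PS	1|0:108449
chr10	109468	.	A	T	.	PASS	.	GT:PS	0|1:108449
chr10	110478	.	A	T	.	PASS	.	GT:PS	0|1:108449
chr10	113820	.	A	T	.	PASS	.	GT:PS	0|1:113820
chr10	114582	.	A	T	.	PASS	.	GT:PS	0|1:113820
chr10	116261	.	A	T	.	PASS	.	GT:PS	0|1:113820
chr10	116793	.	A	T	.	PASS	.	GT:PS	0|1:113820
chr10	116871	.	A	T	.	PASS	.	GT:PS	1|0:113820
chr10	118046	.	A	T	.	PASS	.	GT:PS	0|1:113820
chr10	118129	.	A	T	.	PASS	.	GT:PS	1|0:118129
chr10	118392	.	A	T	.	PASS	.	GT:PS	1|0:118129
chr10	119518	.	A	T	.	PASS	.	GT:PS	1|0:118129
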