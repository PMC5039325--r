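##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5	s6	s7
chr1	100	.	A	C	.	.	.	GT:DP:GQ	0/0:60:40	0/1:72:35	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	200	.	A	AT	.	.	.	GT:DP:GQ	0/0:60:40	0/1:72:35	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	300	.	A	C,G	.	.	.	GT:DP:GQ	0/0:60:40	0/1:72:35	0/2:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	400	.	G	T	.	.	.	GT:DP:GQ	0/0:49:40	0/1:49:35	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	500	.	G	A	.	.	.	GT:DP:GQ	0/0:60:19	0/1:72:19	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	600	.	C	T	.	.	.	GT:DP:GQ	0/0:10:40	0/1:72:35	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	700	.	T	G	.	.	.	GT:DP:GQ	0/0:60:40	0/0:72:35	0/0:55:28	0/0:90:60	0/0:66:44	0/0:58:30	0/0:81:52
chr1	800	.	A	G	.	.	.	GT:DP:GQ	./.:55:30	0/1:72:35	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	900	.	C	G	.	.	.	GT:DP:GQ	0/0:50:20	0/1:50:20	0/1:50:20	1/1:50:20	0/0:50:20	0/1:50:20	0/0:50:20
chr1	1000	.	AT	A	.	.	.	GT:DP:GQ	0/0:60:40	0/1:72:35	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	1100	.	G	C	.	.	.	GT:DP:GQ	1/1:60:40	0/1:72:35	0/1:55:28	1/1:90:60	0/0:66:44	0/1:58:30	0/0:81:52
chr1	1200	.	T	A	.	.	.	GT:DP:GQ	0/1:60:40	0/1:72:35	0/1:55:28	0/1:90:60	0/1:66:44	0/1:58:30	0/1:81:52
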