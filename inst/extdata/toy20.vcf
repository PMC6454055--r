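##fileformat=VCFv4.2
##source=hand-built synthetic filter fixture (two pools, two wild diploids)
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">
##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">
##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	p1	p2	w1	w2
chr1	1000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	2000	.	A	G	110	.	QD=19.9;FS=1;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	3000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=-8.5	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	4000	.	A	G	110	.	QD=30;FS=10.5;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	5000	.	A	G	60	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	6000	.	A	G	110	.	FS=1;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	7000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:40,0	./.:40,1	0/0:.	0/0:.
chr1	8000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:36,2	./.:38,0	0/1:.	0/1:.
chr1	9000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:4,3	./.:20,20	0/1:.	0/1:.
chr1	10000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:0,0	./.:20,20	./.:.	0/1:.
chr1	11000	.	A	G	60	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	12000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:30,10	./.:25,15	0/0:.	0/1:.
chr1	13000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:10,30	./.:15,25	1/1:.	0/1:.
chr1	14000	.	A	G	110	.	QD=10;FS=20;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	15000	.	A	G	60	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	16000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:18,22	./.:21,19	0/1:.	1/1:.
chr1	17000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:40,0	./.:40,0	0/0:.	0/0:.
chr1	18000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:22,18	./.:19,21	0/1:.	0/0:.
chr1	19000	.	A	G	60	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:20,20	./.:20,20	0/1:.	0/1:.
chr1	20000	.	A	G	110	.	QD=30;FS=1;ReadPosRankSum=0	GT:AD	./.:25,15	./.:24,16	0/1:.	0/1:.
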