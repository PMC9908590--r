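id	level	parent_id	name	order
c_adenocarcinoma	class		Adenocarcinoma	1
c_adenoma	class		Adenoma	2
c_normal	class		Normal	3
s_ac01	subtype	c_adenocarcinoma	Poorly differentiated adenocarcinoma	1
s_ac02	subtype	c_adenocarcinoma	Moderately differentiated adenocarcinoma	2
s_ac03	subtype	c_adenocarcinoma	Well differentiated adenocarcinoma	3
s_ac04	subtype	c_adenocarcinoma	Tumor invasion	4
s_ac05	subtype	c_adenocarcinoma	Tumor budding	5
s_ac06	subtype	c_adenocarcinoma	Vascular invasion	6
s_ac07	subtype	c_adenocarcinoma	Nerve invasion	7
s_ac08	subtype	c_adenocarcinoma	Synthetic adenocarcinoma subtype 8	8
s_ac09	subtype	c_adenocarcinoma	Synthetic adenocarcinoma subtype 9	9
s_ad01	subtype	c_adenoma	Low-grade adenoma	1
s_ad02	subtype	c_adenoma	High-grade adenoma	2
s_nm01	subtype	c_normal	Normal	1
r_ac01	reason	s_ac01	Irregular arrangement of glands	1
r_ac02	reason	s_ac02	Mucinous differentiation	2
r_ac03	reason	s_ac03	Vacuolated nuclei	3
r_ac04	reason	s_ac04	Cribriform structure	4
r_ac05	reason	s_ac05	Irregular glandular duct arrangement	5
r_ac06	reason	s_ac06	Necrosis	6
r_ac07	reason	s_ac07	Nucleoli more prominent	7
r_ac08	reason	s_ac08	Round tumor cell nuclei	8
r_ac09	reason	s_ac09	Papillary arrangement	9
r_ac10	reason	s_ac01	Karyorrhexis	10
r_ac11	reason	s_ac02	Thickened chromatin	11
r_ac12	reason	s_ac03	Screen mesh	12
r_ac13	reason	s_ac04	Markedly reduced cytoplasm	13
r_ac14	reason	s_ac05	Infiltration of single or several tumor cells	14
r_ac15	reason	s_ac06	Invasion into the muscularis mucosae	15
r_ac16	reason	s_ac07	Infiltration into the submucosa	16
r_ac17	reason	s_ac08	Tumor budding (grade 1)	17
r_ac18	reason	s_ac09	Polar disorder	18
r_ac19	reason	s_ac01	Synthetic adenocarcinoma feature 1	19
r_ac20	reason	s_ac02	Synthetic adenocarcinoma feature 2	20
r_ac21	reason	s_ac03	Synthetic adenocarcinoma feature 3	21
r_ac22	reason	s_ac04	Synthetic adenocarcinoma feature 4	22
r_ac23	reason	s_ac05	Synthetic adenocarcinoma feature 5	23
r_ac24	reason	s_ac06	Synthetic adenocarcinoma feature 6	24
r_ac25	reason	s_ac07	Synthetic adenocarcinoma feature 7	25
r_ac26	reason	s_ac08	Synthetic adenocarcinoma feature 8	26
r_ac27	reason	s_ac09	Synthetic adenocarcinoma feature 9	27
r_ac28	reason	s_ac01	Synthetic adenocarcinoma feature 10	28
r_ac29	reason	s_ac02	Synthetic adenocarcinoma feature 11	29
r_ac30	reason	s_ac03	Synthetic adenocarcinoma feature 12	30
r_ac31	reason	s_ac04	Synthetic adenocarcinoma feature 13	31
r_ac32	reason	s_ac05	Synthetic adenocarcinoma feature 14	32
r_ac33	reason	s_ac06	Synthetic adenocarcinoma feature 15	33
r_ac34	reason	s_ac07	Synthetic adenocarcinoma feature 16	34
r_ad01	reason	s_ad01	Low-grade intraepithelial neoplasia	1
r_ad02	reason	s_ad02	Glands lack mature differentiation	2
r_ad03	reason	s_ad01	Nuclei rod-shaped	3
r_ad04	reason	s_ad02	Nucleus stratified or pseudostratified arrangement	4
r_ad05	reason	s_ad01	Tubular structure	5
r_ad06	reason	s_ad02	Increased epithelial cell hierarchy	6
r_ad07	reason	s_ad01	Nuclei remain polar	7
r_ad08	reason	s_ad02	Synthetic adenoma feature 1	8
r_ad09	reason	s_ad01	Synthetic adenoma feature 2	9
r_ad10	reason	s_ad02	Synthetic adenoma feature 3	10
r_ad11	reason	s_ad01	Synthetic adenoma feature 4	11
r_ad12	reason	s_ad02	Synthetic adenoma feature 5	12
r_ad13	reason	s_ad01	Synthetic adenoma feature 6	13
r_ad14	reason	s_ad02	Synthetic adenoma feature 7	14
r_ad15	reason	s_ad01	Synthetic adenoma feature 8	15
r_ad16	reason	s_ad02	Synthetic adenoma feature 9	16
r_ad17	reason	s_ad01	Synthetic adenoma feature 10	17
r_ad18	reason	s_ad02	Synthetic adenoma feature 11	18
r_ad19	reason	s_ad01	Synthetic adenoma feature 12	19
r_ad20	reason	s_ad02	Synthetic adenoma feature 13	20
r_ad21	reason	s_ad01	Synthetic adenoma feature 14	21
r_ad22	reason	s_ad02	Synthetic adenoma feature 15	22
r_ad23	reason	s_ad01	Synthetic adenoma feature 16	23
r_ad24	reason	s_ad02	Synthetic adenoma feature 17	24
r_ad25	reason	s_ad01	Synthetic adenoma feature 18	25
r_nm01	reason	s_nm01	Fatty tissue	1
r_nm02	reason	s_nm01	Smooth muscle	2
r_nm03	reason	s_nm01	Lymphatic vessel	3
r_nm04	reason	s_nm01	Synthetic normal feature 1	4
r_nm05	reason	s_nm01	Synthetic normal feature 2	5
r_nm06	reason	s_nm01	Synthetic normal feature 3	6
r_nm07	reason	s_nm01	Synthetic normal feature 4	7
r_nm08	reason	s_nm01	Synthetic normal feature 5	8
r_nm09	reason	s_nm01	Synthetic normal feature 6	9
r_nm10	reason	s_nm01	Synthetic normal feature 7	10
r_nm11	reason	s_nm01	Synthetic normal feature 8	11
r_nm12	reason	s_nm01	Synthetic normal feature 9	12
r_nm13	reason	s_nm01	Synthetic normal feature 10	13
r_nm14	reason	s_nm01	Synthetic normal feature 11	14
r_nm15	reason	s_nm01	Synthetic normal feature 12	15
r_nm16	reason	s_nm01	Synthetic normal feature 13	16
r_nm17	reason	s_nm01	Synthetic normal feature 14	17
r_nm18	reason	s_nm01	Synthetic normal feature 15	18
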