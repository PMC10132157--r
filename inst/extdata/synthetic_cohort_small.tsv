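patient_id	site_id	anatomic_site	marker	core_id	h_score	death_year
P001	S01	other	PSMA	c1	4.67672866338917	2012
P001	S01	other	PSMA	c2	0.731943393389064	2012
P001	S02	bone_nonvertebral	PSMA	c1	23.5310509682761	2012
P001	S02	bone_nonvertebral	PSMA	c2	14.0504944544746	2012
P002	S01	bone_nonvertebral	PSMA	c1	12.9917209903637	2006
P002	S01	bone_nonvertebral	PSMA	c2	23.1584678592611	2006
P002	S02	lymph_node	PSMA	c1	7.04509078171532	2006
P002	S02	lymph_node	PSMA	c2	0	2006
P002	S03	lymph_node	PSMA	c1	7.72960321362093	2006
P002	S03	lymph_node	PSMA	c2	0	2006
P002	S04	other	PSMA	c1	168.910179578976	2006
P002	S04	other	PSMA	c2	9.66242868137097	2006
P003	S01	bone_vertebral	PSMA	c1	14.3297667780518	2019
P003	S01	bone_vertebral	PSMA	c2	0	2019
P003	S02	bone_nonvertebral	PSMA	c1	39.0841832871012	2019
P003	S02	bone_nonvertebral	PSMA	c2	40.5925081395789	2019
P003	S03	lymph_node	PSMA	c1	12.0851711136678	2019
P003	S03	lymph_node	PSMA	c2	0	2019
P004	S01	lymph_node	PSMA	c1	13.7403677728459	2017
P004	S01	lymph_node	PSMA	c2	11.0103821945701	2017
P004	S02	bone_vertebral	PSMA	c1	0	2017
P004	S02	bone_vertebral	PSMA	c2	0	2017
P004	S03	bone_vertebral	PSMA	c1	1.6865784817952	2017
P004	S03	bone_vertebral	PSMA	c2	0	2017
P004	S04	bone_nonvertebral	PSMA	c1	108.052126818944	2017
P004	S04	bone_nonvertebral	PSMA	c2	4.24588547700505	2017
P001	S01	other	AR	c1	111.607950585801	2012
P001	S01	other	AR	c2	109.125406759551	2012
P001	S02	bone_nonvertebral	AR	c1	140.146360026626	2012
P001	S02	bone_nonvertebral	AR	c2	163.863642867784	2012
P002	S01	bone_nonvertebral	AR	c1	13.2832158441713	2006
P002	S01	bone_nonvertebral	AR	c2	2.68766281323114	2006
P002	S02	lymph_node	AR	c1	6.04371775700746	2006
P002	S02	lymph_node	AR	c2	0	2006
P002	S03	lymph_node	AR	c1	1.4170431406142	2006
P002	S03	lymph_node	AR	c2	0	2006
P002	S04	other	AR	c1	19.4011912824761	2006
P002	S04	other	AR	c2	0	2006
P003	S01	bone_vertebral	AR	c1	175.14344436909	2019
P003	S01	bone_vertebral	AR	c2	181.223931981597	2019
P003	S02	bone_nonvertebral	AR	c1	134.000286509934	2019
P003	S02	bone_nonvertebral	AR	c2	135.622708756279	2019
P003	S03	lymph_node	AR	c1	164.31526111343	2019
P003	S03	lymph_node	AR	c2	186.423403357583	2019
P004	S01	lymph_node	AR	c1	2.38956895109651	2017
P004	S01	lymph_node	AR	c2	4.61582914304577	2017
P004	S02	bone_vertebral	AR	c1	9.93686529419998	2017
P004	S02	bone_vertebral	AR	c2	6.58442873990985	2017
P004	S03	bone_vertebral	AR	c1	5.04269275178378	2017
P004	S03	bone_vertebral	AR	c2	10.4682952300719	2017
P004	S04	bone_nonvertebral	AR	c1	7.63809718426717	2017
P004	S04	bone_nonvertebral	AR	c2	6.88731424160295	2017
P001	S01	other	SYP	c1	0	2012
P001	S01	other	SYP	c2	0	2012
P001	S02	bone_nonvertebral	SYP	c1	12.3286877855286	2012
P001	S02	bone_nonvertebral	SYP	c2	1.2952196998921	2012
P002	S01	bone_nonvertebral	SYP	c1	118.908811160901	2006
P002	S01	bone_nonvertebral	SYP	c2	132.221893804211	2006
P002	S02	lymph_node	SYP	c1	89.090860146506	2006
P002	S02	lymph_node	SYP	c2	79.7456912627361	2006
P002	S03	lymph_node	SYP	c1	92.9397081376965	2006
P002	S03	lymph_node	SYP	c2	106.70486392609	2006
P002	S04	other	SYP	c1	167.947477442677	2006
P002	S04	other	SYP	c2	171.676418562339	2006
P003	S01	bone_vertebral	SYP	c1	20.0673105694573	2019
P003	S01	bone_vertebral	SYP	c2	5.32051129099122	2019
P003	S02	bone_nonvertebral	SYP	c1	13.6071069838527	2019
P003	S02	bone_nonvertebral	SYP	c2	0	2019
P003	S03	lymph_node	SYP	c1	8.87986438950936	2019
P003	S03	lymph_node	SYP	c2	2.52161076473572	2019
P004	S01	lymph_node	SYP	c1	109.300434028158	2017
P004	S01	lymph_node	SYP	c2	84.7726234755766	2017
P004	S02	bone_vertebral	SYP	c1	153.442774629731	2017
P004	S02	bone_vertebral	SYP	c2	145.217887404188	2017
P004	S03	bone_vertebral	SYP	c1	131.935921401433	2017
P004	S03	bone_vertebral	SYP	c2	143.875111300653	2017
P004	S04	bone_nonvertebral	SYP	c1	200	2017
P004	S04	bone_nonvertebral	SYP	c2	183.487139298696	2017
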