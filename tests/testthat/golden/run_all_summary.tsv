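section	key	value
config	seed	101
config	n_draws	5000
config	gamma	0.5
network	n_tf	50
network	n_mirna	80
network	n_gene	287
network	tf_gene	664
network	tf_mirna	187
network	mirna_gene	1067
network	mirna_tf	62
ffl	n_total	745
ffl	n_TF_FFL	517
dysregulated	n_TF_FFL	33
ffl	n_MIRNA_FFL	163
dysregulated	n_MIRNA_FFL	12
ffl	n_FB_FFL	65
dysregulated	n_FB_FFL	11
dysregulated	n_total	56
dysregulated	sum_equals_total	TRUE
hub	n_hub_ffls	2
systems	cardiovascular	3
systems	endocrine	2
systems	immune	2
systems	nervous	4
systems	skeletal	2
sharing	unassigned	46
sharing	specific	8
sharing	intermediate	1
sharing	general	1
sharing	nodes_shared	6/30
sharing	edges_shared	6/33
pattern	SYNCA	8.46628e-25;1;1;2.07757e-30
pattern	SYNCB	1;9.43372e-26;1.64985e-23;1
pattern	SYNCC	0.473979;0.526536;0.543485;0.457028
pattern_label	SYNCA	consistent
pattern_label	SYNCB	reverse
pattern_label	SYNCC	
drug_inhibitor	drug01	4
drug_inhibitor	drug07	1
drug_inhibitor	drug09	1
drug_inhibitor	drug10	1
drug_inhibitor	drug17	1
drug_inhibitor	drug19	1
drug_inhibitor	drug20	1
drug_reversal	drug01	6
drug_reversal	drug19	4
drug_reversal	drug04	3
drug_reversal	drug18	3
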