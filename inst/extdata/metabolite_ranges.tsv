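metabolite_id	c_min_molar	c_max_molar
atp	0.001	0.01
adp	1e-04	0.001
amp	1e-04	0.001
pi	0.001	0.01
nad	0.001	0.005
nadh	3e-05	5e-04
nadp	1e-06	5e-04
nadph	1e-05	5e-04
coa	1e-04	0.001
glutamate	0.01	0.15
akg	1e-04	0.001
pep	1e-05	5e-04
pyruvate	5e-05	0.005
3pg	1e-04	0.005
fbp	0.001	0.02
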