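item,unit_cost_eur
antispastic_drug_pack,25
gp_visit,27
neurologist_visit,45
physiotherapy_session,22
emergency_visit,150
mri_scan,200
blood_test,15
surgical_procedure,3000
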