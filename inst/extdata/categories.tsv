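category	root_concept_id
DIABETES	diabetes_root
ISCHAEMIC_HEART_DISEASE	ihd_root
HYPERTENSION	htn_root
LUNG_DISEASE	lung_root
CKD	ckd_root
PULMONARY_HYPERTENSION	ph_root
RA	ra_root
PSA	psa_root
AS	as_root
ILD	ild
CTD_ILD	ctd_ild
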