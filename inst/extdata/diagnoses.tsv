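concept_id	preferred_term	synonyms	parent_ids
diabetes_root	Diabetes mellitus	diabetes
t1dm	Type 1 diabetes	type 1 diabetes mellitus|t1dm|insulin dependent diabetes	diabetes_root
t2dm	Type 2 diabetes	type 2 diabetes mellitus|t2dm|non insulin dependent diabetes	diabetes_root
ihd_root	Ischaemic heart disease	ischemic heart disease|coronary artery disease|coronary heart disease
mi	Myocardial infarction	heart attack|nstemi|stemi	ihd_root
angina	Angina	stable angina|angina pectoris	ihd_root
htn_root	Hypertension	high blood pressure|essential hypertension|systemic hypertension
lung_root	Chronic lung disease	pre-existing lung disease|lung disease
copd	COPD	chronic obstructive pulmonary disease|emphysema|chronic bronchitis	lung_root
asthma	Asthma	bronchial asthma	lung_root
bronchiectasis	Bronchiectasis		lung_root
pneumonitis	Pneumonitis		lung_root
pneumonia	Pneumonia	community acquired pneumonia	pneumonitis
ild	Interstitial lung disease	ild|pulmonary interstitial disease	lung_root
pulm_fibrosis	Pulmonary fibrosis	lung fibrosis|idiopathic pulmonary fibrosis	ild
ckd_root	Chronic kidney disease	chronic kidney impairment|chronic renal impairment|renal impairment|ckd
ckd3	CKD stage 3	chronic kidney disease stage 3	ckd_root
ph_root	Pulmonary hypertension	pulmonary arterial hypertension
ra_root	Rheumatoid arthritis	ra
seropos_ra	Seropositive rheumatoid arthritis	seropositive ra|rheumatoid arthritis seropositive	ra_root
seroneg_ra	Seronegative rheumatoid arthritis	seronegative ra	ra_root
psa_root	Psoriatic arthritis	psa|psoriatic arthropathy
as_root	Ankylosing spondylitis	axial spondyloarthritis|axial spa
ctd_root	Connective tissue disease	ctd
sle	Systemic lupus erythematosus	sle|lupus	ctd_root
ssc	Systemic sclerosis	scleroderma	ctd_root
myositis	Myositis	polymyositis|dermatomyositis	ctd_root
sjogren	Sjogren syndrome	sjogrens syndrome|sicca syndrome	ctd_root
ctd_ild	Connective tissue disease associated interstitial lung disease	ctd-ild|ctd associated ild	ctd_root|ild
ra_ild	Rheumatoid arthritis associated interstitial lung disease	ra-ild|ra associated ild	ra_root|ild
osteoarthritis	Osteoarthritis	oa|degenerative joint disease
osteoporosis	Osteoporosis
gout	Gout
fibromyalgia	Fibromyalgia
depression	Depression
hypothyroid	Hypothyroidism	underactive thyroid
psoriasis	Psoriasis
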