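heading_synonym	kind
rheumatological diagnoses	DIAGNOSIS_LIST
rheumatology diagnoses	DIAGNOSIS_LIST
rheumatological diagnosis	DIAGNOSIS_LIST
other diagnoses	DIAGNOSIS_LIST
other diagnosis	DIAGNOSIS_LIST
diagnoses	DIAGNOSIS_LIST
problem list	DIAGNOSIS_LIST
comorbidities	DIAGNOSIS_LIST
current medications	CURRENT_MEDS
current medication	CURRENT_MEDS
medications	CURRENT_MEDS
current drugs	CURRENT_MEDS
drug history	CURRENT_MEDS
current dmards	CURRENT_MEDS
previous dmards	PAST_MEDS
previous medications	PAST_MEDS
past medications	PAST_MEDS
previous drugs	PAST_MEDS
discontinued medications	PAST_MEDS
planned medications	PLANNED_MEDS
planned treatment	PLANNED_MEDS
medications to commence	PLANNED_MEDS
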