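generic_name	brands	classes
prednisolone		GLUCOCORTICOID
prednisone		GLUCOCORTICOID
hydrocortisone		GLUCOCORTICOID
dexamethasone		GLUCOCORTICOID
methylprednisolone	Depo-Medrone	GLUCOCORTICOID
methotrexate	Metoject|Maxtrex	IMMUNOSUPPRESSANT
azathioprine	Imuran	IMMUNOSUPPRESSANT
leflunomide	Arava	IMMUNOSUPPRESSANT
mycophenolate	CellCept|mycophenolate mofetil	IMMUNOSUPPRESSANT
ciclosporin	Neoral	IMMUNOSUPPRESSANT
tacrolimus	Prograf	IMMUNOSUPPRESSANT
sulfasalazine	Salazopyrin	IMMUNOSUPPRESSANT
adalimumab	Humira|Amgevita|Imraldi	BIOLOGIC
etanercept	Enbrel|Benepali	BIOLOGIC
infliximab	Remicade|Inflectra|Remsima	BIOLOGIC
rituximab	Mabthera|Rixathon	BIOLOGIC
tocilizumab	RoActemra	BIOLOGIC
abatacept	Orencia	BIOLOGIC
certolizumab	Cimzia	BIOLOGIC
golimumab	Simponi	BIOLOGIC
secukinumab	Cosentyx	BIOLOGIC
ustekinumab	Stelara	BIOLOGIC
belimumab	Benlysta	BIOLOGIC
tofacitinib	Xeljanz	SMALL_MOLECULE_IS
baricitinib	Olumiant	SMALL_MOLECULE_IS
upadacitinib	Rinvoq	SMALL_MOLECULE_IS
cyclophosphamide	Cytoxan	CYCLOPHOSPHAMIDE
hydroxychloroquine	Plaquenil	NON_SCORING
paracetamol		NON_SCORING
ibuprofen	Brufen	NON_SCORING
naproxen	Naprosyn	NON_SCORING
omeprazole	Losec	NON_SCORING
folic acid		NON_SCORING
alendronic acid	Fosamax	NON_SCORING
amlodipine	Istin	NON_SCORING
ramipril	Tritace	NON_SCORING
atorvastatin	Lipitor	NON_SCORING
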