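token	per_day
twice daily	2
three times daily	3
four times daily	4
alternate days	0.5
every other day	0.5
od	1
bd	2
bid	2
tds	3
tid	3
qds	4
qid	4
daily	1
mane	1
nocte	1
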