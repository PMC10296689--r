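table_id,level,n_low,n_high
orr,responder,28,6
orr,non_responder,12,6
dcr,controlled,39,10
dcr,not_controlled,1,2
age,ge65,9,2
age,lt65,31,10
smoking,never,28,10
smoking,former_current,12,2
brain,yes,12,6
brain,no,28,6
bone,yes,17,7
bone,no,23,5
liver,yes,8,3
liver,no,32,9
contralateral_lung,yes,11,7
contralateral_lung,no,29,5
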