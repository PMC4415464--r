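# SYNTHETIC per-question stage tables for a two-stage family-history
# questionnaire validation study (four conditions).  These counts are a
# synthetic reconstruction built for examples and tests: the published
# per-question stage-1 tables of the motivating study are not available as
# text, so only the selected questions' stage totals echo the real study.
# Columns: stage-1 case counts tp/fn, fixed control counts fp/tn; stage-2
# case counts tp2/fn2 on the selected question's row only; excluded flags
# questions dropped for sparse responses before threshold derivation.
condition,question,excluded,tp,fn,fp,tn,tp2,fn2
diabetes,q1,0,44,12,45,285,,
diabetes,q2,0,20,36,50,280,,
diabetes,q3,0,54,2,40,290,63,2
diabetes,q4a,1,2,54,3,327,,
ihd,q1,0,46,12,48,272,,
ihd,q2,0,54,4,50,270,52,4
ihd,q3,0,40,18,46,274,,
ihd,q8,0,38,20,44,276,,
breast,q1,0,8,18,55,175,,
breast,q12a,0,12,14,10,220,,
breast,q12b,0,10,16,6,224,,
breast,q2,0,9,17,50,180,,
breast,q6,0,14,12,25,205,,
breast,q7,0,16,10,35,195,,
breast,q8,0,19,7,39,191,14,8
colorectal,q10,0,22,4,30,280,15,5
colorectal,q11,0,12,14,28,282,,
colorectal,q2,0,6,20,40,270,,
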