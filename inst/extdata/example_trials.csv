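session_id,trial,distance_m,disk_state,response,outcome,is_reversal
S01,1,0.700,reflecting,yes,hit,FALSE
S01,2,0.950,nonreflecting,no,correct_rejection,FALSE
S01,3,0.950,reflecting,yes,hit,FALSE
S01,4,1.200,nonreflecting,no,correct_rejection,FALSE
S01,5,1.200,nonreflecting,no,correct_rejection,FALSE
S01,6,1.200,nonreflecting,no,correct_rejection,FALSE
S01,7,1.200,nonreflecting,no,correct_rejection,FALSE
S01,8,1.200,reflecting,yes,hit,FALSE
S01,9,1.450,nonreflecting,no,correct_rejection,FALSE
S01,10,1.450,reflecting,yes,hit,FALSE
S01,11,1.700,nonreflecting,no,correct_rejection,FALSE
S01,12,1.700,reflecting,yes,hit,FALSE
S01,13,1.950,nonreflecting,no,correct_rejection,FALSE
S01,14,1.950,reflecting,yes,hit,FALSE
S01,15,2.200,reflecting,yes,hit,FALSE
S01,16,2.450,reflecting,yes,hit,FALSE
S01,17,2.700,reflecting,yes,hit,FALSE
S01,18,2.950,nonreflecting,no,correct_rejection,FALSE
S01,19,2.950,reflecting,no,miss,TRUE
S01,20,2.700,reflecting,no,miss,FALSE
S01,21,2.450,reflecting,yes,hit,TRUE
S01,22,2.700,nonreflecting,no,correct_rejection,FALSE
S01,23,2.700,reflecting,yes,hit,FALSE
S01,24,2.950,reflecting,no,miss,TRUE
S01,25,2.700,nonreflecting,yes,false_alarm,FALSE
S01,26,2.200,reflecting,yes,hit,TRUE
S01,27,2.450,nonreflecting,no,correct_rejection,FALSE
S01,28,2.450,reflecting,no,miss,TRUE
S01,29,2.200,nonreflecting,no,correct_rejection,FALSE
S01,30,2.200,nonreflecting,no,correct_rejection,FALSE
S01,31,2.200,nonreflecting,no,correct_rejection,FALSE
S01,32,2.200,nonreflecting,no,correct_rejection,FALSE
S01,33,2.200,nonreflecting,no,correct_rejection,FALSE
S01,34,2.200,reflecting,yes,hit,TRUE
S01,35,2.450,nonreflecting,no,correct_rejection,FALSE
S01,36,2.450,reflecting,no,miss,TRUE
S01,37,2.200,nonreflecting,no,correct_rejection,FALSE
S01,38,2.200,nonreflecting,no,correct_rejection,FALSE
S01,39,2.200,reflecting,yes,hit,TRUE
S01,40,2.450,nonreflecting,no,correct_rejection,FALSE
S01,41,2.450,nonreflecting,no,correct_rejection,FALSE
S01,42,2.450,nonreflecting,no,correct_rejection,FALSE
S01,43,2.450,reflecting,no,miss,TRUE
S01,44,2.200,reflecting,yes,hit,TRUE
S01,45,2.450,reflecting,yes,hit,FALSE
S01,46,2.700,nonreflecting,no,correct_rejection,FALSE
S01,47,2.700,nonreflecting,yes,false_alarm,TRUE
S01,48,2.200,reflecting,no,miss,FALSE
S01,49,1.950,reflecting,yes,hit,TRUE
S02,1,0.700,nonreflecting,no,correct_rejection,FALSE
S02,2,0.700,nonreflecting,no,correct_rejection,FALSE
S02,3,0.700,reflecting,yes,hit,FALSE
S02,4,0.950,nonreflecting,no,correct_rejection,FALSE
S02,5,0.950,nonreflecting,no,correct_rejection,FALSE
S02,6,0.950,nonreflecting,no,correct_rejection,FALSE
S02,7,0.950,nonreflecting,no,correct_rejection,FALSE
S02,8,0.950,nonreflecting,no,correct_rejection,FALSE
S02,9,0.950,nonreflecting,no,correct_rejection,FALSE
S02,10,0.950,nonreflecting,no,correct_rejection,FALSE
S02,11,0.950,nonreflecting,no,correct_rejection,FALSE
S02,12,0.950,nonreflecting,no,correct_rejection,FALSE
S02,13,0.950,reflecting,yes,hit,FALSE
S02,14,1.200,reflecting,yes,hit,FALSE
S02,15,1.450,reflecting,yes,hit,FALSE
S02,16,1.700,reflecting,no,miss,TRUE
S02,17,1.450,reflecting,yes,hit,TRUE
S02,18,1.700,nonreflecting,no,correct_rejection,FALSE
S02,19,1.700,reflecting,no,miss,TRUE
S02,20,1.450,nonreflecting,no,correct_rejection,FALSE
S02,21,1.450,nonreflecting,no,correct_rejection,FALSE
S02,22,1.450,reflecting,yes,hit,TRUE
S02,23,1.700,reflecting,yes,hit,FALSE
S02,24,1.950,reflecting,yes,hit,FALSE
S02,25,2.200,reflecting,no,miss,TRUE
S02,26,1.950,reflecting,yes,hit,TRUE
S02,27,2.200,nonreflecting,yes,false_alarm,TRUE
S02,28,1.700,nonreflecting,no,correct_rejection,FALSE
S02,29,1.700,nonreflecting,no,correct_rejection,FALSE
S02,30,1.700,nonreflecting,no,correct_rejection,FALSE
S02,31,1.700,nonreflecting,yes,false_alarm,FALSE
S02,32,1.200,reflecting,yes,hit,TRUE
S02,33,1.450,reflecting,yes,hit,FALSE
S02,34,1.700,reflecting,yes,hit,FALSE
S02,35,1.950,nonreflecting,no,correct_rejection,FALSE
S02,36,1.950,nonreflecting,no,correct_rejection,FALSE
S02,37,1.950,nonreflecting,no,correct_rejection,FALSE
S02,38,1.950,reflecting,yes,hit,FALSE
S02,39,2.200,nonreflecting,yes,false_alarm,TRUE
S02,40,1.700,nonreflecting,no,correct_rejection,FALSE
S02,41,1.700,nonreflecting,yes,false_alarm,FALSE
S02,42,1.200,nonreflecting,no,correct_rejection,FALSE
S02,43,1.200,reflecting,yes,hit,TRUE
S02,44,1.450,reflecting,yes,hit,FALSE
S02,45,1.700,nonreflecting,no,correct_rejection,FALSE
S02,46,1.700,reflecting,yes,hit,FALSE
S02,47,1.950,nonreflecting,no,correct_rejection,FALSE
S02,48,1.950,reflecting,yes,hit,FALSE
S02,49,2.200,nonreflecting,no,correct_rejection,FALSE
S02,50,2.200,reflecting,yes,hit,FALSE
S02,51,2.450,nonreflecting,no,correct_rejection,FALSE
S02,52,2.450,nonreflecting,no,correct_rejection,FALSE
S02,53,2.450,reflecting,no,miss,TRUE
S02,54,2.200,reflecting,no,miss,FALSE
S02,55,1.950,reflecting,yes,hit,TRUE
S03,1,0.700,reflecting,yes,hit,FALSE
S03,2,0.950,nonreflecting,no,correct_rejection,FALSE
S03,3,0.950,reflecting,yes,hit,FALSE
S03,4,1.200,reflecting,yes,hit,FALSE
S03,5,1.450,reflecting,yes,hit,FALSE
S03,6,1.700,reflecting,yes,hit,FALSE
S03,7,1.950,nonreflecting,no,correct_rejection,FALSE
S03,8,1.950,nonreflecting,yes,false_alarm,TRUE
S03,9,1.450,reflecting,yes,hit,TRUE
S03,10,1.700,reflecting,yes,hit,FALSE
S03,11,1.950,reflecting,no,miss,TRUE
S03,12,1.700,nonreflecting,no,correct_rejection,FALSE
S03,13,1.700,nonreflecting,no,correct_rejection,FALSE
S03,14,1.700,nonreflecting,no,correct_rejection,FALSE
S03,15,1.700,reflecting,no,miss,FALSE
S03,16,1.450,reflecting,no,miss,FALSE
S03,17,1.200,nonreflecting,yes,false_alarm,FALSE
S03,18,0.700,nonreflecting,no,correct_rejection,FALSE
S03,19,0.700,reflecting,no,miss,FALSE
S03,20,0.700,nonreflecting,yes,false_alarm,FALSE
S03,21,0.700,nonreflecting,no,correct_rejection,FALSE
S03,22,0.700,nonreflecting,no,correct_rejection,FALSE
S03,23,0.700,reflecting,yes,hit,TRUE
S03,24,0.950,reflecting,no,miss,TRUE
S03,25,0.700,reflecting,yes,hit,TRUE
S03,26,0.950,nonreflecting,no,correct_rejection,FALSE
S03,27,0.950,reflecting,yes,hit,FALSE
S03,28,1.200,nonreflecting,yes,false_alarm,TRUE
S03,29,0.700,nonreflecting,no,correct_rejection,FALSE
S03,30,0.700,nonreflecting,yes,false_alarm,FALSE
S03,31,0.700,reflecting,no,miss,FALSE
S03,32,0.700,nonreflecting,no,correct_rejection,FALSE
S03,33,0.700,nonreflecting,yes,false_alarm,FALSE
S03,34,0.700,nonreflecting,no,correct_rejection,FALSE
S03,35,0.700,reflecting,yes,hit,TRUE
S03,36,0.950,reflecting,no,miss,TRUE
S03,37,0.700,nonreflecting,no,correct_rejection,FALSE
S03,38,0.700,nonreflecting,no,correct_rejection,FALSE
S03,39,0.700,reflecting,no,miss,FALSE
S03,40,0.700,nonreflecting,yes,false_alarm,FALSE
S03,41,0.700,nonreflecting,yes,false_alarm,FALSE
S03,42,0.700,nonreflecting,no,correct_rejection,FALSE
S03,43,0.700,nonreflecting,no,correct_rejection,FALSE
S03,44,0.700,reflecting,yes,hit,TRUE
S03,45,0.950,nonreflecting,no,correct_rejection,FALSE
S03,46,0.950,reflecting,yes,hit,FALSE
S03,47,1.200,nonreflecting,yes,false_alarm,TRUE
S03,48,0.700,nonreflecting,yes,false_alarm,FALSE
S03,49,0.700,reflecting,yes,hit,TRUE
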