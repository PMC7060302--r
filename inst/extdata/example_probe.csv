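time_iso,counts,duration_s,view,is_background
2019-03-04T09:30:00,301,600,single,true
2019-03-04T10:00:00,20876,60,single,false
2019-03-04T12:00:00,16638,60,single,false
2019-03-04T14:00:00,13942,60,single,false
2019-03-04T16:00:00,11260,60,single,false
2019-03-04T18:00:00,9732,60,single,false
2019-03-04T20:00:00,8075,60,single,false
2019-03-04T22:00:00,7292,60,single,false
2019-03-05T00:00:00,6446,60,single,false
2019-03-05T02:00:00,5704,60,single,false
2019-03-05T04:00:00,5285,60,single,false
2019-03-05T06:00:00,5078,60,single,false
2019-03-05T08:00:00,4589,60,single,false
2019-03-05T10:00:00,4255,60,single,false
2019-03-05T16:00:00,3597,60,single,false
2019-03-05T22:00:00,3110,60,single,false
2019-03-06T04:00:00,2700,60,single,false
2019-03-06T10:00:00,2409,60,single,false
2019-03-06T16:00:00,2133,60,single,false
2019-03-06T22:00:00,1889,60,single,false
2019-03-07T04:00:00,1686,60,single,false
2019-03-07T10:00:00,1564,60,single,false
2019-03-07T16:00:00,1334,60,single,false
2019-03-07T22:00:00,1182,60,single,false
2019-03-08T04:00:00,1048,60,single,false
2019-03-08T10:00:00,888,60,single,false
2019-03-08T16:00:00,868,60,single,false
2019-03-08T22:00:00,715,60,single,false
2019-03-09T04:00:00,658,60,single,false
2019-03-09T10:00:00,623,60,single,false
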