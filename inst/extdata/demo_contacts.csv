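cow_id,encountered_cow_id,start_date,start_time,end_date,end_time,duration_s
1,2,9/03/2009,18:49:34,9/03/2009,18:49:35,1
1,2,9/03/2009,18:52:57,9/03/2009,18:56:00,183
1,2,9/03/2009,18:56:05,9/03/2009,18:56:21,16
1,2,9/03/2009,18:56:48,9/03/2009,18:58:38,110
1,2,9/03/2009,18:56:05,9/03/2009,18:56:21,16
1,2,9/03/2009,19:01:03,9/03/2009,19:01:06,3
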