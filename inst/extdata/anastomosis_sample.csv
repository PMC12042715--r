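attempt,date,stage1_mistakes,stage2_mistakes,stage3_mistakes,total_score,stage1_time,stage2_time,stage3_time,total_time
1,2024-04-18,-,-,1,1,776,203,"1,159","2,138"
2,2024-04-19,-,1,1,2,"1,002",859,752,"2,613"
3,2024-04-18,-,-,-,0,408,562,901,"1,871"
4,2024-04-20,-,1,-,0,484,648,"1,925","3,057"
5,2024-04-24,-,-,-,0,619,452,"1,865","2,936"
6,2024-04-24,-,5,-,5,-,-,-,0
7,2024-04-25,-,-,1,1,690,646,"1,458","2,794"
8,2024-04-24,-,-,1,1,404,397,840,"1,641"
9,2024-04-26,-,-,2,1,435,135,"1,028","1,598"
10,2024-04-26,-,-,-,0,446,946,690,"2,082"
11,2024-04-26,-,-,-,0,519,593,822,"1,934"
12,2024-04-29,-,-,-,1,246,505,"1,188","1,939"
13,2024-04-30,5,-,-,5,-,-,-,0
14,2024-04-30,-,5,-,5,-,-,-,0
15,2024-04-30,-,-,-,0,472,508,962,"1,942"
16,2024-05-02,-,5,-,5,-,-,-,0
17,2024-05-02,-,1,1,2,711,648,"1,079","2,438"
18,2024-05-02,-,1,-,1,366,573,"1,039","1,978"
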