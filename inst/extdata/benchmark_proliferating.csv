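image,detected,tp,fp,fn,sensitivity_printed,fpf_printed,user_p
D1,3,3,0,0,1.00,0.00,3
D1-PT1,3,3,0,1,0.75,0.00,4
D1-CV2,4,4,0,0,1.00,0.00,4
D2,22,18,4,1,0.94,0.18,19
D2-PT1,27,23,4,1,0.96,0.14,24
D2-CV1,11,8,3,0,1.00,0.27,8
D3,27,24,3,1,0.96,0.11,25
D3-PT1,12,11,1,7,0.61,0.08,18
D3-CV1,41,39,2,1,0.97,0.04,40
D4,98,96,2,27,0.78,0.02,123
D4-PT1,105,102,3,14,0.87,0.02,116
D4-CV1,58,57,1,7,0.89,0.01,64
D5,3,2,1,0,1.00,0.33,2
D5-PT1,1,1,0,1,0.5,0.00,2
D5-CV1,1,1,0,0,1.00,0.00,1
D6-PT1,90,77,13,3,0.96,0.14,80
D6-CV1,65,61,4,5,0.92,0.06,66
D7,40,37,3,2,0.94,0.075,39
D7-PT1,26,25,1,0,1.00,0.03,25
D7-CV1,24,20,4,1,0.95,0.16,21
D8,138,120,18,2,0.98,0.13,122
D8-PT1,93,72,21,3,0.96,0.22,75
D8-CV1,55,50,5,1,0.98,0.09,51
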