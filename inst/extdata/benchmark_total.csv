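image,detected,tp,fp,fn,sensitivity_printed,fpf_printed,user_p
D1,230,221,9,22,0.91,0.039,243
D1-PT1,210,188,22,20,0.90,0.1,208
D1-CV1,302,269,33,38,0.88,0.1,307
D2,223,201,22,14,0.93,0.09,215
D2-PT1,212,166,46,9,0.95,0.21,175
D2-CV1,230,200,30,17,0.92,0.13,217
D3,299,230,69,10,0.96,0.23,240
D3-PT1,268,206,62,13,0.94,0.23,219
D3-CV1,269,216,53,13,0.94,0.19,229
D4,229,212,17,33,0.87,0.07,245
D4-PT1,216,198,18,15,0.93,0.08,213
D4-CV1,237,218,19,10,0.95,0.08,228
D5,226,189,49,12,0.94,0.21,201
D5-PT1,217,210,7,15,0.93,0.03,225
D5-CV1,237,197,40,5,0.97,0.16,202
D6-PT1,216,186,30,11,0.94,0.13,197
D6-CV1,224,186,38,14,0.93,0.16,200
D7,230,191,39,11,0.94,0.17,202
D7-PT1,236,190,46,3,0.98,0.19,193
D7-CV1,218,204,14,8,0.96,0.06,212
D8,229,197,32,6,0.97,0.13,203
D8-PT1,214,177,37,10,0.95,0.17,187
D8-CV1,208,174,34,16,0.91,0.16,190
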