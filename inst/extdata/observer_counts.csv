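image,observer,category,count
D5,1,total_hc,219
D5,2,total_hc,198
D5,3,total_hc,189
D5,1,total_nonhc,162
D5,2,total_nonhc,150
D5,3,total_nonhc,257
D5,1,proliferating_hc,4
D5,2,proliferating_hc,4
D5,3,proliferating_hc,2
D5,1,proliferating_nonhc,399
D5,2,proliferating_nonhc,357
D5,3,proliferating_nonhc,188
D5-PT1,1,total_hc,266
D5-PT1,2,total_hc,213
D5-PT1,3,total_hc,314
D5-PT1,4,total_hc,225
D5-PT1,1,total_nonhc,164
D5-PT1,2,total_nonhc,170
D5-PT1,3,total_nonhc,150
D5-PT1,4,total_nonhc,272
D5-PT1,1,proliferating_hc,2
D5-PT1,2,proliferating_hc,3
D5-PT1,3,proliferating_hc,4
D5-PT1,4,proliferating_hc,2
D5-PT1,1,proliferating_nonhc,473
D5-PT1,2,proliferating_nonhc,442
D5-PT1,3,proliferating_nonhc,453
D5-PT1,4,proliferating_nonhc,188
D5-CV1,1,total_hc,265
D5-CV1,2,total_hc,227
D5-CV1,3,total_hc,303
D5-CV1,4,total_hc,202
D5-CV1,1,total_nonhc,167
D5-CV1,2,total_nonhc,137
D5-CV1,3,total_nonhc,127
D5-CV1,4,total_nonhc,214
D5-CV1,1,proliferating_hc,2
D5-CV1,2,proliferating_hc,2
D5-CV1,3,proliferating_hc,1
D5-CV1,4,proliferating_hc,1
D5-CV1,1,proliferating_nonhc,444
D5-CV1,2,proliferating_nonhc,415
D5-CV1,3,proliferating_nonhc,184
D5-CV1,4,proliferating_nonhc,371
D6-PT1,1,total_hc,215
D6-PT1,2,total_hc,207
D6-PT1,3,total_hc,276
D6-PT1,4,total_hc,197
D6-PT1,1,total_nonhc,174
D6-PT1,2,total_nonhc,165
D6-PT1,3,total_nonhc,135
D6-PT1,4,total_nonhc,178
D6-PT1,1,proliferating_hc,90
D6-PT1,2,proliferating_hc,103
D6-PT1,3,proliferating_hc,107
D6-PT1,4,proliferating_hc,77
D6-PT1,1,proliferating_nonhc,319
D6-PT1,2,proliferating_nonhc,295
D6-PT1,3,proliferating_nonhc,292
D6-PT1,4,proliferating_nonhc,99
D6-CV1,1,total_hc,232
D6-CV1,2,total_hc,213
D6-CV1,3,total_hc,291
D6-CV1,4,total_hc,200
D6-CV1,1,total_nonhc,163
D6-CV1,2,total_nonhc,127
D6-CV1,3,total_nonhc,139
D6-CV1,4,total_nonhc,208
D6-CV1,1,proliferating_hc,81
D6-CV1,2,proliferating_hc,78
D6-CV1,3,proliferating_hc,92
D6-CV1,4,proliferating_hc,62
D6-CV1,1,proliferating_nonhc,348
D6-CV1,2,proliferating_nonhc,276
D6-CV1,3,proliferating_nonhc,345
D6-CV1,4,proliferating_nonhc,127
D7,1,total_hc,243
D7,2,total_hc,230
D7,3,total_hc,264
D7,4,total_hc,202
D7,1,total_nonhc,134
D7,2,total_nonhc,153
D7,3,total_nonhc,103
D7,4,total_nonhc,191
D7,1,proliferating_hc,39
D7,2,proliferating_hc,42
D7,3,proliferating_hc,49
D7,4,proliferating_hc,39
D7,1,proliferating_nonhc,347
D7,2,proliferating_nonhc,280
D7,3,proliferating_nonhc,326
D7,4,proliferating_nonhc,168
D7-PT1,1,total_hc,249
D7-PT1,2,total_hc,214
D7-PT1,3,total_hc,282
D7-PT1,4,total_hc,193
D7-PT1,1,total_nonhc,146
D7-PT1,2,total_nonhc,113
D7-PT1,3,total_nonhc,116
D7-PT1,4,total_nonhc,251
D7-PT1,1,proliferating_hc,33
D7-PT1,2,proliferating_hc,34
D7-PT1,3,proliferating_hc,37
D7-PT1,4,proliferating_hc,24
D7-PT1,1,proliferating_nonhc,383
D7-PT1,2,proliferating_nonhc,317
D7-PT1,3,proliferating_nonhc,359
D7-PT1,4,proliferating_nonhc,151
D7-CV1,1,total_hc,264
D7-CV1,2,total_hc,195
D7-CV1,3,total_hc,289
D7-CV1,4,total_hc,212
D7-CV1,1,total_nonhc,153
D7-CV1,2,total_nonhc,124
D7-CV1,3,total_nonhc,122
D7-CV1,4,total_nonhc,214
D7-CV1,1,proliferating_hc,28
D7-CV1,2,proliferating_hc,27
D7-CV1,3,proliferating_hc,33
D7-CV1,4,proliferating_hc,21
D7-CV1,1,proliferating_nonhc,421
D7-CV1,2,proliferating_nonhc,355
D7-CV1,3,proliferating_nonhc,398
D7-CV1,4,proliferating_nonhc,188
D8,1,total_hc,237
D8,2,total_hc,216
D8,3,total_hc,254
D8,4,total_hc,203
D8,1,total_nonhc,189
D8,2,total_nonhc,117
D8,3,total_nonhc,142
D8,4,total_nonhc,181
D8,1,proliferating_hc,147
D8,2,proliferating_hc,143
D8,3,proliferating_hc,158
D8,4,proliferating_hc,122
D8,1,proliferating_nonhc,284
D8,2,proliferating_nonhc,200
D8,3,proliferating_nonhc,242
D8,4,proliferating_nonhc,242
D8-PT1,1,total_hc,242
D8-PT1,2,total_hc,200
D8-PT1,3,total_hc,274
D8-PT1,4,total_hc,187
D8-PT1,1,total_nonhc,255
D8-PT1,2,total_nonhc,195
D8-PT1,3,total_nonhc,197
D8-PT1,4,total_nonhc,319
D8-PT1,1,proliferating_hc,102
D8-PT1,2,proliferating_hc,109
D8-PT1,3,proliferating_hc,134
D8-PT1,4,proliferating_hc,75
D8-PT1,1,proliferating_nonhc,402
D8-PT1,2,proliferating_nonhc,321
D8-PT1,3,proliferating_nonhc,348
D8-PT1,4,proliferating_nonhc,388
D8-CV1,1,total_hc,230
D8-CV1,2,total_hc,185
D8-CV1,3,total_hc,253
D8-CV1,4,total_hc,190
D8-CV1,1,total_nonhc,116
D8-CV1,2,total_nonhc,69
D8-CV1,3,total_nonhc,78
D8-CV1,4,total_nonhc,207
D8-CV1,1,proliferating_hc,61
D8-CV1,2,proliferating_hc,53
D8-CV1,3,proliferating_hc,65
D8-CV1,4,proliferating_hc,51
D8-CV1,1,proliferating_nonhc,315
D8-CV1,2,proliferating_nonhc,235
D8-CV1,3,proliferating_nonhc,273
D8-CV1,4,proliferating_nonhc,398
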