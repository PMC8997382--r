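parameter,level,gh2ax_ihc_low,gh2ax_ihc_high,gh2ax_if_low,gh2ax_if_high,bp1_ihc_low,bp1_ihc_high,bp1_if_low,bp1_if_high
sex,male,21,28,24,25,26,23,28,21
sex,female,21,14,18,17,14,21,14,21
location,gastric,35,23,30,28,29,29,27,31
location,non_gastric,7,19,12,14,11,15,15,11
histology,spindle,36,32,36,32,35,33,35,33
histology,epithelioid_mixed,6,10,6,10,5,11,7,9
size,under_5cm,33,23,31,25,30,26,30,26
size,over_5cm,8,18,10,16,10,16,11,15
nih,low_very_low,34,14,32,16,30,18,31,17
nih,intermediate,8,9,7,10,8,9,6,11
nih,high,0,19,3,16,2,17,5,14
nccn,none_very_low,29,11,25,15,25,15,24,16
nccn,low,12,4,13,3,11,5,12,4
nccn,moderate,1,10,2,9,2,9,2,9
nccn,high,0,17,2,15,2,15,4,13
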