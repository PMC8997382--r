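parameter,level,gh2ax_ihc_low,gh2ax_ihc_high,bp1_ihc_low,bp1_ihc_high
sex,male,65,69,63,71
sex,female,72,79,79,72
location,gastric,97,91,90,98
location,non_gastric,40,57,52,45
histology,spindle,108,98,118,88
histology,epithelioid_mixed,27,49,23,53
size,under_5cm,63,53,72,44
size,over_5cm,74,95,70,99
nih,low_very_low,52,30,63,19
nih,intermediate,50,59,51,58
nih,high,35,59,28,66
nccn,none_very_low,38,17,41,14
nccn,low,51,37,60,28
nccn,moderate,19,45,17,47
nccn,high,28,49,23,54
genotype,other_or_wild,100,102,110,92
genotype,kit_ex11_del,37,46,32,51
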