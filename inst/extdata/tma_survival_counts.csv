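parameter,level,n_case,n_event,hr,ci_lower,ci_upper
sex,male,134,30,,,
sex,female,151,31,,,
age,under_70,214,41,,,
age,70_plus,71,20,,,
location,gastric,188,30,1,,
location,non_gastric,97,31,1.365,0.815,2.289
histology,spindle,206,32,1,,
histology,epithelioid_mixed,77,29,1.8,1.048,3.093
size,under_5cm,116,10,,,
size,5_to_10cm,119,25,,,
size,10cm_plus,50,26,,,
mitoses,0_5,197,24,,,
mitoses,6_10,43,9,,,
mitoses,over_10,45,28,,,
nccn,none_very_low,55,2,1,,
nccn,low,88,8,2.05,0.431,9.743
nccn,moderate,64,8,2.518,0.514,12.339
nccn,high,77,43,14.612,3.355,63.641
genotype,other_or_wild,202,32,1,,
genotype,kit_ex11_del,83,29,2.12,1.23,3.568
dual_marker,low_both,100,14,1,,
dual_marker,high_either_or_both,185,47,0.815,0.426,1.559
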