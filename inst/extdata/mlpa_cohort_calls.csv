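sample_id,sex,site,nih_risk,nccn_risk,rb1_call,brca2_call,chek2_call
G01,male,gastric,high,high,normal,normal,heterozygous_deletion
G02,female,gastric,low_very_low,none_very_low,normal,heterozygous_deletion,heterozygous_deletion
G03,male,gastric,low_very_low,low,normal,heterozygous_deletion,heterozygous_deletion
G04,male,gastric,intermediate,moderate,normal,normal,heterozygous_deletion
G05,male,gastric,intermediate,moderate,normal,normal,heterozygous_deletion
G06,male,gastric,intermediate,moderate,normal,normal,heterozygous_deletion
G07,male,gastric,intermediate,moderate,normal,normal,heterozygous_deletion
G08,male,gastric,intermediate,moderate,normal,normal,heterozygous_deletion
G09,male,gastric,intermediate,moderate,normal,normal,heterozygous_deletion
G10,male,gastric,intermediate,low,normal,normal,heterozygous_deletion
G11,male,gastric,intermediate,low,normal,normal,heterozygous_deletion
G12,male,gastric,intermediate,low,normal,normal,heterozygous_deletion
G13,male,gastric,intermediate,low,normal,normal,heterozygous_deletion
G14,male,gastric,intermediate,low,normal,normal,heterozygous_deletion
G15,male,gastric,low_very_low,low,normal,normal,heterozygous_deletion
G16,male,gastric,low_very_low,low,normal,normal,heterozygous_deletion
G17,male,gastric,low_very_low,low,normal,normal,heterozygous_deletion
G18,male,gastric,low_very_low,none_very_low,normal,normal,heterozygous_deletion
G19,male,gastric,low_very_low,none_very_low,normal,normal,heterozygous_deletion
G20,male,gastric,low_very_low,none_very_low,normal,normal,heterozygous_deletion
G21,male,gastric,high,high,normal,normal,normal
G22,male,gastric,intermediate,moderate,normal,normal,normal
G23,male,gastric,intermediate,low,normal,normal,normal
G24,female,gastric,low_very_low,none_very_low,normal,normal,normal
G25,female,gastric,low_very_low,none_very_low,normal,normal,normal
G26,female,gastric,low_very_low,none_very_low,normal,normal,normal
NG01,male,intestinal,high,high,heterozygous_deletion,heterozygous_deletion,heterozygous_deletion
NG02,female,intestinal,high,high,heterozygous_deletion,heterozygous_deletion,heterozygous_deletion
NG03,female,intestinal,high,high,heterozygous_deletion,normal,heterozygous_deletion
NG04,female,intestinal,high,high,heterozygous_deletion,normal,heterozygous_deletion
NG05,male,intestinal,high,high,normal,heterozygous_deletion,heterozygous_deletion
NG06,male,intestinal,low_very_low,none_very_low,normal,normal,heterozygous_deletion
NG07,female,intestinal,low_very_low,none_very_low,normal,normal,heterozygous_deletion
NG08,female,intestinal,low_very_low,none_very_low,normal,normal,heterozygous_deletion
NG09,female,intestinal,low_very_low,none_very_low,normal,normal,heterozygous_deletion
NG10,female,intestinal,low_very_low,none_very_low,normal,normal,heterozygous_deletion
NG11,female,intestinal,low_very_low,none_very_low,normal,normal,heterozygous_deletion
NG12,male,intestinal,high,high,normal,normal,normal
NG13,male,intestinal,high,high,normal,normal,normal
NG14,female,intestinal,high,high,normal,normal,normal
NG15,female,intestinal,intermediate,none_very_low,normal,normal,normal
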