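# NCCN-referenced AFIP (Miettinen-Lasota) site-specific risk table.
# Non-gastric tumors (intestinal, omental, other) use the small-intestine
# column, matching the gastric vs non-gastric binarization used throughout.
# Size bins are (0,2], (2,5], (5,10], (10,Inf) cm; mitosis bins [0,5] and
# (5,Inf) per 50 HPF.  The gastric <=2 cm / >5 mitoses cell had too few
# cases in the source series to support a risk estimate and is encoded
# insufficient_data.
scheme: nccn
edition: AFIP (Miettinen-Lasota 2006) prognostic groups as referenced by NCCN
size_breaks_cm: [2.0, 5.0, 10.0]
mitosis_breaks_per50hpf: [5]
levels:
  gastric:
    - [none, insufficient_data]        # size <= 2 cm : mitoses <=5, >5
    - [very_low, moderate]             # 2 < size <= 5
    - [low, high]                      # 5 < size <= 10
    - [moderate, high]                 # size > 10
  non_gastric:
    - [none, high]
    - [low, high]
    - [moderate, high]
    - [high, high]
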