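# NIH consensus risk scheme (Fletcher 2002) encoded as a size x mitosis grid.
# Size bins are (0,2], (2,5], (5,10], (10,Inf) cm; mitosis bins are
# [0,5], (5,10], (10,Inf) per 50 HPF.  Upper bounds inclusive; the published
# table leaves exact boundary membership open, recorded here as config so a
# different edition can be swapped in.
scheme: nih
edition: Fletcher 2002 consensus scheme (size x mitotic count, site-agnostic)
size_breaks_cm: [2.0, 5.0, 10.0]
mitosis_breaks_per50hpf: [5, 10]
levels:
  - [very_low, intermediate, high]      # size <= 2 cm
  - [low, intermediate, high]           # 2 < size <= 5
  - [intermediate, high, high]          # 5 < size <= 10
  - [high, high, high]                  # size > 10
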