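# Default model inputs: carrier consumption percentiles (g/day, German
# National Nutritional Survey II), dietary vitamin D intake (ug/day),
# intake/serum targets and the intake-to-serum conversion factor.
#
# Dietary p5/p95 values are NOT survey figures: they are synthetic
# placeholders (only the gender means are published). Downstream risk
# envelopes built from them carry ordering information only.
carriers:
  bread:
    p5:   {men: 46.0,  women: 43.0}
    mean: {men: 180.0, women: 134.0}
    p95:  {men: 377.0, women: 270.0}
  milk:
    p5:   {men: 16.0,  women: 22.0}
    mean: {men: 222.0, women: 203.0}
    p95:  {men: 712.0, women: 555.0}
  juice:
    p5:   {men: 0.0,    women: 0.0}
    mean: {men: 270.0,  women: 232.0}
    p95:  {men: 1200.0, women: 1000.0}
intake:
  dietary:
    p5:   {men: 1.0, women: 1.0}   # synthetic placeholder
    mean: {men: 3.4, women: 2.8}
    p95:  {men: 7.0, women: 6.0}   # synthetic placeholder
  supplement_mean: 0.3
targets:
  intake:
    IOM: 15.0
    DGE: 20.0
    UL: 100.0
  serum:
    serum50: 50.0
    serum75: 75.0
conversion_factor: 2.32
serum_model:
  annual_mean: 45.0
  amplitude: 17.2
  trough_month: 1
  region_offset: 0.0
  region: germany
thresholds:
  ul_intake: 100.0
  intoxication_serum: 500.0
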