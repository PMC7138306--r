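# Published severity-grade cut points for accidents involving roadside
# trees. Grade intervals are right-closed: I <= b1 < II <= b2 < III <= b3 < IV.
# The mixed-traffic ASI cut points are linear in the truck proportion w.
version: 1
fixed:
  cra:        {b1: 60.0, b2: 73.0, b3: 96.0}   # g
  asi_car:    {b1: 1.0,  b2: 1.78, b3: 2.21}
  asi_truck:  {b1: 1.0,  b2: 1.54, b3: 2.02}
mixed:
  b1: 1.0
  b2_intercept: 1.78
  b2_slope: -0.24
  b3_intercept: 2.21
  b3_slope: -0.19
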