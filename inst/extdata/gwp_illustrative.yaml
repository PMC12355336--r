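# Illustrative GWP config: the default Kyoto-gas GWPs are built in; this
# file adds round refrigerant GWPs for demonstrations and tests.
gwp:
  "R-404A": 3943
  "R-134a": 1300
  "R-410A": 1924
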