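# Oral toxicity constants for the assessed PTEs.
# rfd: reference dose, mg/(kg d); sf: cancer slope factor, (kg d)/mg.
rfd:
  Fe: 0.7
  Mn: 0.14
  Cu: 0.04
  Zn: 0.3
  Al: 1
  As: 0.0003
  Se: 0.005
  Cd: 0.0005
  Li: 0.002
  B: 0.2
  Ba: 0.2
  Sb: 0.0004
  Ni: 0.02
  Co: 0.0003
  Mo: 0.005
sf:
  As: 1.5
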