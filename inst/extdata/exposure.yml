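# Drinking-water ingestion exposure parameters per population group.
# These are commonly used Chinese technical-guideline values shipped as
# editable defaults; site-specific assessments should supply their own.
# IR  L/day   oral water ingestion rate
# EF  d/year  exposure frequency
# ED  years   exposure duration
# BW  kg      body weight
# LE  years   life expectancy (carcinogenic averaging time)
groups:
  - {group: children, IR: 1.0, EF: 365, ED: 6,  BW: 16, LE: 70}
  - {group: men,      IR: 2.2, EF: 365, ED: 30, BW: 65, LE: 70}
  - {group: women,    IR: 1.7, EF: 365, ED: 30, BW: 56, LE: 70}
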