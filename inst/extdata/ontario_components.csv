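community,population,isolation,vulnerability,readiness,ssm
Dryden,0.81,0.94,0.29,0.80,0.71
Elliot Lake,0.68,0.45,0.35,0.60,0.52
Fort Frances,1.00,0.93,0.30,0.80,0.76
Goderich,0.23,0.22,0.29,0.60,0.34
Haileybury,0.56,0.41,0.34,0.60,0.48
Hawkesbury,0.26,0.16,0.28,0.60,0.33
Kapuskasing,0.46,0.44,0.33,0.40,0.41
Kenora,0.87,0.56,0.29,0.80,0.63
Kincardine,0.25,0.27,0.30,0.80,0.41
Kirkland Lake,0.26,0.26,0.32,0.80,0.41
Parry Sound,0.21,0.25,0.30,1.00,0.44
Perth,0.19,0.22,0.27,0.80,0.37
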