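community,age,sex,alone,vandix,vulnerability
Dryden,0.08,0.46,0.08,0.53,0.29
Elliot Lake,0.13,0.46,0.12,0.67,0.35
Fort Frances,0.10,0.46,0.10,0.52,0.30
Goderich,0.11,0.49,0.09,0.47,0.29
Haileybury,0.12,0.51,0.10,0.67,0.34
Hawkesbury,0.09,0.50,0.08,0.48,0.28
Kapuskasing,0.10,0.47,0.12,0.64,0.33
Kenora,0.09,0.42,0.09,0.55,0.29
Kincardine,0.12,0.50,0.10,0.49,0.30
Kirkland Lake,0.10,0.46,0.10,0.63,0.32
Parry Sound,0.18,0.47,0.10,0.52,0.30
Perth,0.08,0.43,0.08,0.49,0.27
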