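community,aware,education,telemedicine,fp_adequate,momentum,score
Dryden,yes,yes,yes,yes,no,0.8
Elliot Lake,yes,no,yes,yes,no,0.6
Fort Frances,yes,yes,yes,yes,no,0.8
Goderich,yes,no,yes,yes,no,0.6
Haileybury,yes,yes,yes,no,no,0.6
Hawkesbury,no,yes,yes,yes,no,0.6
Kapuskasing,no,no,yes,yes,no,0.4
Kenora,yes,yes,yes,yes,no,0.8
Kincardine,yes,yes,yes,yes,no,0.8
Kirkland Lake,yes,yes,yes,yes,no,0.8
Parry Sound,yes,yes,yes,yes,yes,1.0
Perth,yes,yes,yes,yes,no,0.8
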