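label	smd	ci_low	ci_high
healthy_fatigued_low_25ohd	-0.77	-1.13	-0.42
primary_care_low_25ohd	-0.13	-0.55	0.28
chronic_fatigue_syndrome	0.12	-0.47	0.71
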