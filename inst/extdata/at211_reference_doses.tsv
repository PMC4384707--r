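organ	time_h	activity_kbq	dose_mgy
kidney_cortex	1	1.7	0.29
kidney_medulla	1	1.7	0.29
liver	1	1.7	0.23
lungs	1	1.7	1.9
spleen	1	1.7	0.86
thyroid	1	1.7	23
kidney_cortex	6	1.7	2.6
kidney_medulla	6	1.7	2.6
liver	6	1.7	2.0
lungs	6	1.7	16
spleen	6	1.7	5.7
thyroid	6	1.7	320
kidney_cortex	168	1.7	7.6
kidney_medulla	168	1.7	7.6
liver	168	1.7	6.3
lungs	168	1.7	50
spleen	168	1.7	14
thyroid	168	1.7	1800
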