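sample_id	dataset_id	platform_label	class_label
F1_S01	F1	chipA	healthy
F1_S02	F1	chipA	disease1
F1_S03	F1	chipA	disease2
F1_S04	F1	chipA	disease3
F1_S05	F1	chipA	healthy
F1_S06	F1	chipA	disease1
F1_S07	F1	chipA	disease2
F1_S08	F1	chipA	disease3
F1_S09	F1	chipA	healthy
F1_S10	F1	chipA	disease1
F2_S01	F2	chipB	healthy
F2_S02	F2	chipB	disease1
F2_S03	F2	chipB	disease2
F2_S04	F2	chipB	disease3
F2_S05	F2	chipB	healthy
F2_S06	F2	chipB	disease1
F2_S07	F2	chipB	disease2
F2_S08	F2	chipB	disease3
F3_S01	F3	chipA	healthy
F3_S02	F3	chipA	disease1
F3_S03	F3	chipA	disease2
F3_S04	F3	chipA	disease3
F3_S05	F3	chipA	healthy
F3_S06	F3	chipA	disease1
F3_S07	F3	chipA	disease2
F3_S08	F3	chipA	disease3
F4_S01	F4	chipC	healthy
F4_S02	F4	chipC	disease1
F4_S03	F4	chipC	disease2
F4_S04	F4	chipC	disease3
F4_S05	F4	chipC	healthy
F4_S06	F4	chipC	disease1
F4_S07	F4	chipC	disease2
F4_S08	F4	chipC	disease3
F5_S01	F5	chipB	healthy
F5_S02	F5	chipB	disease1
F5_S03	F5	chipB	disease2
F5_S04	F5	chipB	disease3
F5_S05	F5	chipB	healthy
F5_S06	F5	chipB	disease1
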