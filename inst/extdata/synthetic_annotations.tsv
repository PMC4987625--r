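type	label	start	end
domain	carrier	1	183
domain	antigen	184	438
contact	cp1	5	5
contact	cp2	15	15
contact	cp3	30	30
contact	cp4	60	60
contact	cp5	100	100
contact	cp6	120	120
contact	cp7	130	130
contact	cp8	140	140
contact	cp9	141	141
contact	cp10	143	143
contact	cp11	180	180
contact	cp12	200	200
contact	cp13	210	210
contact	cp14	215	215
contact	cp15	220	220
contact	cp16	230	230
contact	cp17	240	240
contact	cp18	245	245
contact	cp19	248	248
contact	cp20	250	250
contact	cp21	252	252
contact	cp22	254	254
contact	cp23	255	255
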