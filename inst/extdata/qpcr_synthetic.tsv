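target	tissue	replicate	target_ct	ref_ct
miR-9	brain	1	18.1	15.0
miR-9	brain	2	18.3	15.1
miR-9	brain	3	18.0	14.9
miR-9	liver	1	24.6	15.2
miR-9	liver	2	24.9	15.0
miR-9	liver	3	24.7	15.1
miR-9	gill	1	23.1	15.0
miR-9	gill	2	23.4	15.2
miR-9	gill	3	23.0	14.8
Novel-37	brain	1	22.0	15.0
Novel-37	brain	2	22.2	15.1
Novel-37	brain	3	21.9	15.0
Novel-37	liver	1	22.5	15.1
Novel-37	liver	2	22.4	15.0
Novel-37	liver	3	22.6	15.2
Novel-37	gill	1	22.1	15.0
Novel-37	gill	2	22.3	15.1
Novel-37	gill	3	22.0	14.9
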