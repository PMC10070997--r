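allele	frequency_percent
A*01:01	16.2
A*02:01	27.2
A*03:01	13.1
A*24:02	9.0
B*07:02	12.1
B*08:01	9.3
B*35:01	6.6
B*37:01	3.23
B*38:01	1.72
B*40:01	5.4
B*73:01	0.4
C*07:01	15.3
C*07:02	14.4
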