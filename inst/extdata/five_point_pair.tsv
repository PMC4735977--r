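probe_id	s1	s2	s3	s4	s5
probe_x_at	0.1	0.3	0.5	0.7	0.9
probe_y_at	0.3	0.9	0.5	0.1	0.7
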