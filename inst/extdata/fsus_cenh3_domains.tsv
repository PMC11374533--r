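chr	chr_size_mb	cen_start_mb	cen_end_mb	cen_size_mb	centfs_arrays_mb
1	47	35.9	37.3	1.4	1.3
2	51	16.7	17.5	0.8	3.0
3	40	30.1	30.5	0.4	4.9
4	64	19.0	20.5	1.5	3.2
5	40	19.4	20.0	0.6	1.5
6	46	19.8	21.3	1.5	1.5
7	45	21.1	21.6	0.5	4.0
8	43	11.2	12.0	0.8	1.0
9	54	24.4	25.4	1.0	3.7
10	56	31.6	32.6	1.0	3.5
11	62	41.5	42.3	0.8	1.0
12	69	45.8	47.2	1.4	4.0
13	53	19.9	20.7	0.8	2.8
14	50	26.7	27.1	0.4	4.0
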