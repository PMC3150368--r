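group1	group2	fst	lambda_printed
HapMap CEU	Southern Sweden	0.000545	1.55
HapMap CEU	Smaland with the islands	0.000673	1.67
HapMap CEU	Western Sweden	0.000627	1.63
HapMap CEU	Stockholm	0.000585	1.59
HapMap CEU	East Middle Sweden	0.000672	1.67
HapMap CEU	North Middle Sweden	0.001018	2.02
HapMap CEU	Middle Norrland	0.001309	2.31
HapMap CEU	Upper Norrland	0.002587	3.59
HapMap CEU	Finns	0.005320	6.32
Southern Sweden	Smaland with the islands	0.000158	1.16
Southern Sweden	Western Sweden	0.000225	1.23
Southern Sweden	Stockholm	0.000180	1.18
Southern Sweden	East Middle Sweden	0.000237	1.24
Southern Sweden	North Middle Sweden	0.000574	1.57
Southern Sweden	Middle Norrland	0.000906	1.91
Southern Sweden	Upper Norrland	0.002187	3.19
Southern Sweden	Finns	0.004633	5.63
Smaland with the islands	Western Sweden	0.000179	1.18
Smaland with the islands	Stockholm	0.000112	1.11
Smaland with the islands	East Middle Sweden	0.000164	1.16
Smaland with the islands	North Middle Sweden	0.000494	1.49
Smaland with the islands	Middle Norrland	0.000814	1.81
Smaland with the islands	Upper Norrland	0.002063	3.06
Smaland with the islands	Finns	0.004318	5.32
Western Sweden	Stockholm	0.000160	1.16
Western Sweden	East Middle Sweden	0.000215	1.22
Western Sweden	North Middle Sweden	0.000500	1.50
Western Sweden	Middle Norrland	0.000842	1.84
Western Sweden	Upper Norrland	0.002112	3.11
Western Sweden	Finns	0.004599	5.60
Stockholm	East Middle Sweden	0.000022	1.02
Stockholm	North Middle Sweden	0.000227	1.23
Stockholm	Middle Norrland	0.000496	1.50
Stockholm	Upper Norrland	0.001686	2.69
Stockholm	Finns	0.003808	4.81
East Middle Sweden	North Middle Sweden	0.000195	1.20
East Middle Sweden	Middle Norrland	0.000512	1.51
East Middle Sweden	Upper Norrland	0.001704	2.70
East Middle Sweden	Finns	0.003661	4.66
North Middle Sweden	Middle Norrland	0.000448	1.45
North Middle Sweden	Upper Norrland	0.001674	2.67
North Middle Sweden	Finns	0.003665	4.67
Middle Norrland	Upper Norrland	0.001146	2.15
Middle Norrland	Finns	0.003855	4.86
Upper Norrland	Finns	0.004613	5.61
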