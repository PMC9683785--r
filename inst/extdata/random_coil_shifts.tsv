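type	atom	delta_rc
A	CA	52.5
R	CA	56
N	CA	53.1
D	CA	54.2
C	CA	58.2
Q	CA	55.7
E	CA	56.6
G	CA	45.1
H	CA	55
I	CA	61.1
L	CA	55.1
K	CA	56.2
M	CA	55.4
F	CA	57.7
P	CA	63.3
S	CA	58.3
T	CA	61.8
W	CA	57.5
Y	CA	57.9
V	CA	62.2
A	CO	177.8
R	CO	176.3
N	CO	175.2
D	CO	176.3
C	CO	174.6
Q	CO	176
E	CO	176.6
G	CO	174.9
H	CO	174.1
I	CO	176.4
L	CO	177.6
K	CO	176.6
M	CO	176.3
F	CO	175.8
P	CO	177.3
S	CO	174.6
T	CO	174.7
W	CO	176.1
Y	CO	175.9
V	CO	176.3
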