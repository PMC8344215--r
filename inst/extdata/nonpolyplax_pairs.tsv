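gene	mrca_arrangement	derived_arrangement	species	genus
N	atp8-atp6-N	E-cob-S1-S2-N	Microthoracius praelongiceps	Microthoracius
N	atp8-atp6-N	cob-S1-N-E-M	Pediculus schaeffi	Pediculus
N	atp8-atp6-N	S1-N-E	Pediculus capitis	Pediculus
N	atp8-atp6-N	S1-N-E	Pediculus humanus	Pediculus
N	atp8-atp6-N	T-~nad1-Q-N-C	Pedicinus badii	Pedicinus
N	atp8-atp6-N	T-~nad1-Q-N-G-nad3-W	Pedicinus obtusus	Pedicinus
E	E-cob-S1-S2	cob-S1-N-E-M	Pediculus schaeffi	Pediculus
E	E-cob-S1-S2	F-nad6-E-M	Pthirus pubis	Pthirus
E	E-cob-S1-S2	S1-N-E	Pediculus capitis	Pediculus
E	E-cob-S1-S2	S1-N-E	Pediculus humanus	Pediculus
S1	E-cob-S1-S2	D-Y-cox2-S1-S2-P-cox3-A	Haematopinus apri	Haematopinus
S1	E-cob-S1-S2	D-Y-cox2-S1-S2-P-cox3-A	Haematopinus suis	Haematopinus
S1	E-cob-S1-S2	D-Y-cox2-S1-S2-P-cox3-A	Haematopinus asini	Haematopinus
S1	E-cob-S1-S2	S1-N-E	Pediculus capitis	Pediculus
S1	E-cob-S1-S2	S1-N-E	Pediculus humanus	Pediculus
S2	E-cob-S1-S2	D-Y-cox2-S1-S2-P-cox3-A	Haematopinus apri	Haematopinus
S2	E-cob-S1-S2	D-Y-cox2-S1-S2-P-cox3-A	Haematopinus suis	Haematopinus
S2	E-cob-S1-S2	D-Y-cox2-S1-S2-P-cox3-A	Haematopinus asini	Haematopinus
S2	E-cob-S1-S2	G-nad3-V-W-S2	Pthirus pubis	Pthirus
I	I-cox1-L2	P-nad2-I	Pediculus schaeffi	Pediculus
I	I-cox1-L2	P-nad2-I	Pediculus capitis	Pediculus
I	I-cox1-L2	P-nad2-I	Pediculus humanus	Pediculus
I	I-cox1-L2	P-nad2-I	Pthirus pubis	Pthirus
I	I-cox1-L2	R-nad4L-P-cox3-I	Pedicinus obtusus	Pedicinus
L2	I-cox1-L2	L2-rrnS-C	Pediculus schaeffi	Pediculus
L2	I-cox1-L2	L2-rrnS-C	Pediculus capitis	Pediculus
L2	I-cox1-L2	L2-rrnS-C	Pediculus humanus	Pediculus
D	D-Y-cox2-nad6	T-D-H-R-nad4L	Pthirus pubis	Pthirus
D	D-Y-cox2-nad6	T-D-H	Pediculus schaeffi	Pediculus
D	D-Y-cox2-nad6	T-D-H	Pediculus capitis	Pediculus
D	D-Y-cox2-nad6	T-D-H	Pediculus humanus	Pediculus
D	D-Y-cox2-nad6	G-nad3-W-D-A-V	Pedicinus badii	Pedicinus
D	D-Y-cox2-nad6	D-A-M-F-nad6	Pedicinus obtusus	Pedicinus
P	R-nad4L-P-cox3-A	P-nad2-I	Pthirus pubis	Pthirus
P	R-nad4L-P-cox3-A	P-nad2-I	Pediculus schaeffi	Pediculus
P	R-nad4L-P-cox3-A	P-nad2-I	Pediculus capitis	Pediculus
P	R-nad4L-P-cox3-A	P-nad2-I	Pediculus humanus	Pediculus
A	R-nad4L-P-cox3-A	G-nad3-W-D-A-V	Pedicinus badii	Pedicinus
A	R-nad4L-P-cox3-A	D-A-M-F-nad6	Pedicinus obtusus	Pedicinus
Q	Q-~nad1-T-G-nad3-W	Q-N-E	Pediculus humanus	Pediculus
Q	Q-~nad1-T-G-nad3-W	T-~nad1-Q-N-C	Pedicinus badii	Pedicinus
Q	Q-~nad1-T-G-nad3-W	T-~nad1-Q-N-G-nad3-W	Pedicinus obtusus	Pedicinus
T	Q-~nad1-T-G-nad3-W	T-~nad1-Q-N-C	Pedicinus badii	Pedicinus
T	Q-~nad1-T-G-nad3-W	T-~nad1-Q-N-G-nad3-W	Pedicinus obtusus	Pedicinus
T	Q-~nad1-T-G-nad3-W	D-Y-cox2-T	Hoplopleura kitti	Hoplopleura
T	Q-~nad1-T-G-nad3-W	R-nad4L-P-cox3-A-T	Hoplopleura akanezumi	Hoplopleura
T	Q-~nad1-T-G-nad3-W	T-D-H-R-nad4L	Pthirus pubis	Pthirus
T	Q-~nad1-T-G-nad3-W	T-D-H	Pediculus schaeffi	Pediculus
T	Q-~nad1-T-G-nad3-W	T-D-H	Pediculus capitis	Pediculus
T	Q-~nad1-T-G-nad3-W	T-D-H	Pediculus humanus	Pediculus
G	Q-~nad1-T-G-nad3-W	G-nad4L-V	Pediculus schaeffi	Pediculus
G	Q-~nad1-T-G-nad3-W	G-nad4L-V	Pediculus capitis	Pediculus
G	Q-~nad1-T-G-nad3-W	G-nad4L-V	Pediculus humanus	Pediculus
W	Q-~nad1-T-G-nad3-W	C-nad6-W-L2	Hoplopleura kitti	Hoplopleura
W	Q-~nad1-T-G-nad3-W	C-nad6-W-L2	Hoplopleura akanezumi	Hoplopleura
W	Q-~nad1-T-G-nad3-W	G-nad3-V-W-S2	Pthirus pubis	Pthirus
H	H-nad5-F	T-D-H-R-nad4L	Pthirus pubis	Pthirus
H	H-nad5-F	T-D-H	Pediculus schaeffi	Pediculus
H	H-nad5-F	T-D-H	Pediculus capitis	Pediculus
H	H-nad5-F	T-D-H	Pediculus humanus	Pediculus
F	H-nad5-F	F-nad6-E-M	Pthirus pubis	Pthirus
F	H-nad5-F	M-F-nad6	Pedicinus badii	Pedicinus
F	H-nad5-F	D-A-M-F-nad6	Pedicinus obtusus	Pedicinus
C	rrnS-C	C-nad6-W-L2	Hoplopleura kitti	Hoplopleura
C	rrnS-C	C-nad6-W-L2	Hoplopleura akanezumi	Hoplopleura
C	rrnS-C	T-~nad1-Q-N-C	Pedicinus badii	Pedicinus
C	rrnS-C	atp8-atp6-C	Pedicinus obtusus	Pedicinus
M	M-L1-rrnL-V	R-nad4L-nad6-M	Haematopinus apri	Haematopinus
M	M-L1-rrnL-V	R-nad4L-nad6-M	Haematopinus suis	Haematopinus
M	M-L1-rrnL-V	F-nad6-E-M	Pthirus pubis	Pthirus
M	M-L1-rrnL-V	cob-S1-N-E-M	Pediculus schaeffi	Pediculus
M	M-L1-rrnL-V	M-F-nad6	Pedicinus badii	Pedicinus
M	M-L1-rrnL-V	D-A-M-F-nad6	Pedicinus obtusus	Pedicinus
L1	M-L1-rrnL-V	L1-rrnS-C	Pediculus schaeffi	Pediculus
L1	M-L1-rrnL-V	L1-rrnS-C	Pediculus capitis	Pediculus
L1	M-L1-rrnL-V	L1-rrnS-C	Pediculus humanus	Pediculus
V	M-L1-rrnL-V	G-nad3-V-W-S2	Pthirus pubis	Pthirus
V	M-L1-rrnL-V	G-nad3-W-D-A-V	Pedicinus badii	Pedicinus
V	M-L1-rrnL-V	nad2-Y-cox2-V	Pedicinus obtusus	Pedicinus
V	M-L1-rrnL-V	G-nad4L-V	Pediculus schaeffi	Pediculus
V	M-L1-rrnL-V	G-nad4L-V	Pediculus capitis	Pediculus
V	M-L1-rrnL-V	G-nad4L-V	Pediculus humanus	Pediculus
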