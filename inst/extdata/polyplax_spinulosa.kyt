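#taxon=Polyplax spinulosa
#genus=Polyplax
# spiny rat louse; trnL1/trnL2 identities swapped relative to P. reclinata
atp8-atp6
E-cob-I
cox1-L1
~T-D-Y-cox2-nad6-A
R-nad4L-P-cox3
~nad1-G-nad3-W
Q-nad2-N
K-nad4
H-nad5-F
S1-S2-rrnS-C
M-L2-rrnL-V
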