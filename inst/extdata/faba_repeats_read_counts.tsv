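class	pairs
LTR/Gypsy	29358977
VicSatellite	20274464
LTR	16974274
LTR/Copia	8090787
rRNA	1986302
Ogre	1708252
Other/simple	1199173
Uncharacterized	1054668
Mobile element	411832
DNA/En-Spm	332062
Retroelement	92278
Non-LTR	53835
Other	45904
DNA	40982
DNA/MuDR	36393
DNA/hAT	34576
LINE	21923
Satellite	9917
DNA/Harbinger	8519
tRNA	7049
DNA/TcMar	6118
DNA/Mite	3643
RC/Helitron	1874
SINE	883
DNA/hAT-Ac	815
DNA/Stowaway	344
DNA/Tourist	55
Other/Centromeric	52
DNA/TcMar-Pogo	6
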