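# Synthetic stand-in for a 37-lectin microarray layout: standard lectin
# names with abbreviated glycan-binding annotations. Used as the default
# lectin universe by the simulators; not measured data.
lectin	specificity
AAL	Fuca1-6GlcNAc, Fuca1-3(Galb1-4)GlcNAc
ACA	Galb1-3GalNAca-Ser/Thr (T antigen)
BPL	Galb1-3GalNAc, terminal GalNAc
ConA	High-mannose, a-Man, a-Glc
DBA	GalNAca1-3GalNAc, Tn antigen
DSA	GlcNAcb1-4GlcNAc oligomers, LacNAc
ECA	Galb1-4GlcNAc (LacNAc)
EEL	Gala1-3Gal (B antigen)
GNA	Mana1-3Man, high-mannose
GSL-I	aGal, aGalNAc
GSL-II	Terminal GlcNAc
HHL	High-mannose
Jacalin	Galb1-3GalNAca-Ser/Thr, sialyl-T
LCA	a-Man with core fucose
LEL	GlcNAc oligomers
LTL	Fuca1-3GlcNAc, LeX
MAL-I	Galb1-4GlcNAc, Neu5Aca2-3Gal
MAL-II	Neu5Aca2-3Gal
MPL	Galb1-3GalNAc, T antigen
NPA	Mana1-6Man
PHA-E	Bisecting GlcNAc, biantennary N-glycan
PHA-E+L	Bisecting GlcNAc, bi/tri-antennary complex N-glycan with outer Gal
PHA-L	Tri/tetra-antennary complex N-glycan
PNA	Galb1-3GalNAc (T antigen)
PSA	a-Man with core fucose
PTL-I	aGalNAc, Tn antigen
PTL-II	Gal, T antigen
PWM	GlcNAc oligomers
RCA120	Galb1-4GlcNAc
SBA	Terminal GalNAca/b1-3/6Gal, (GalNAc)n
SJA	Terminal GalNAc, Gal
SNA	Neu5Aca2-6Gal/GalNAc
STL	GlcNAc oligomers, LacNAc
UEA-I	Fuca1-2Galb1-4GlcNAc (type II H antigen)
VVA	Terminal GalNAc, Tn antigen
WFA	Terminal GalNAc, GalNAca/b1-3/6Gal, (GalNAc)n
WGA	GlcNAc, Neu5Ac
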