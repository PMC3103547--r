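# Backbone-independent rotamer library: AA chi1 chi2 chi3 chi4 (degrees).
# Canonical gauche-/trans/gauche+ chi1 values with common chi2+ states.
# Gly and Ala build without rotamers.
ARG -60 180 180 180
ARG 180 180 180 180
ARG  60 180 180 180
ARG -60 -60 180 180
ASN -60 -30 NA NA
ASN 180  30 NA NA
ASN  60 -30 NA NA
ASP -60   0 NA NA
ASP 180  30 NA NA
ASP  60   0 NA NA
CYS -60 NA NA NA
CYS 180 NA NA NA
CYS  60 NA NA NA
GLN -60 180   0 NA
GLN 180 180   0 NA
GLN  60 180   0 NA
GLN -60 -60 -30 NA
GLU -60 180   0 NA
GLU 180 180   0 NA
GLU  60 180   0 NA
GLU -60 -60   0 NA
HIS -60 -70 NA NA
HIS 180  70 NA NA
HIS  60 -70 NA NA
HIS -60  90 NA NA
ILE -60 170 NA NA
ILE 180 170 NA NA
ILE  60 170 NA NA
ILE -60 -60 NA NA
LEU -60 175 NA NA
LEU 180  65 NA NA
LEU  60 175 NA NA
LYS -60 180 180 180
LYS 180 180 180 180
LYS  60 180 180 180
LYS -60 -60 180 180
MET -60 180  75 NA
MET 180 180  75 NA
MET  60 180 -75 NA
MET -60 -60 -75 NA
PHE -60  90 NA NA
PHE 180  80 NA NA
PHE  60  90 NA NA
PRO  30 -35 NA NA
PRO -25  35 NA NA
SER -60 NA NA NA
SER 180 NA NA NA
SER  60 NA NA NA
THR -60 NA NA NA
THR 180 NA NA NA
THR  60 NA NA NA
TRP -60  90 NA NA
TRP 180 -105 NA NA
TRP  60 -90 NA NA
TYR -60  90 NA NA
TYR 180  80 NA NA
TYR  60  90 NA NA
VAL 175 NA NA NA
VAL -60 NA NA NA
VAL  60 NA NA NA
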