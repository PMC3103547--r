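# ff_a: bundled nonbonded parameter set (charges e, sigma A,
# epsilon kcal/mol, GB radius A). Ionizable side chains in fully
# ionized form (Asp/Glu -1; Lys/Arg/His +1); Tyr/Cys neutral.
CHARGE ALA N     -0.4000 N
CHARGE ALA CA     0.4000 C
CHARGE ALA C      0.6000 C
CHARGE ALA O     -0.6000 O
CHARGE ALA CB     0.0000 C
CHARGE ARG N     -0.4000 N
CHARGE ARG CA     0.4000 C
CHARGE ARG C      0.6000 C
CHARGE ARG O     -0.6000 O
CHARGE ARG CB     0.0000 C
CHARGE ARG CG     0.0000 C
CHARGE ARG CD     0.1000 C
CHARGE ARG NE    -0.4000 N
CHARGE ARG CZ     0.6000 C
CHARGE ARG NH1    0.3500 N
CHARGE ARG NH2    0.3500 N
CHARGE ASN N     -0.4000 N
CHARGE ASN CA     0.4000 C
CHARGE ASN C      0.6000 C
CHARGE ASN O     -0.6000 O
CHARGE ASN CB     0.3000 C
CHARGE ASN CG     0.5500 C
CHARGE ASN OD1   -0.5500 O
CHARGE ASN ND2   -0.3000 N
CHARGE ASP N     -0.4000 N
CHARGE ASP CA     0.4000 C
CHARGE ASP C      0.6000 C
CHARGE ASP O     -0.6000 O
CHARGE ASP CB     0.0000 C
CHARGE ASP CG     0.4000 C
CHARGE ASP OD1   -0.7000 O
CHARGE ASP OD2   -0.7000 O
CHARGE CYS N     -0.4000 N
CHARGE CYS CA     0.4000 C
CHARGE CYS C      0.6000 C
CHARGE CYS O     -0.6000 O
CHARGE CYS CB     0.2000 C
CHARGE CYS SG    -0.2000 S
CHARGE GLN N     -0.4000 N
CHARGE GLN CA     0.4000 C
CHARGE GLN C      0.6000 C
CHARGE GLN O     -0.6000 O
CHARGE GLN CB     0.0000 C
CHARGE GLN CG     0.3000 C
CHARGE GLN CD     0.5500 C
CHARGE GLN OE1   -0.5500 O
CHARGE GLN NE2   -0.3000 N
CHARGE GLU N     -0.4000 N
CHARGE GLU CA     0.4000 C
CHARGE GLU C      0.6000 C
CHARGE GLU O     -0.6000 O
CHARGE GLU CB     0.0000 C
CHARGE GLU CG     0.0000 C
CHARGE GLU CD     0.4000 C
CHARGE GLU OE1   -0.7000 O
CHARGE GLU OE2   -0.7000 O
CHARGE GLY N     -0.4000 N
CHARGE GLY CA     0.4000 C
CHARGE GLY C      0.6000 C
CHARGE GLY O     -0.6000 O
CHARGE HIS N     -0.4000 N
CHARGE HIS CA     0.4000 C
CHARGE HIS C      0.6000 C
CHARGE HIS O     -0.6000 O
CHARGE HIS CB     0.0000 C
CHARGE HIS CG     0.1000 C
CHARGE HIS ND1    0.2500 N
CHARGE HIS CD2    0.1000 C
CHARGE HIS CE1    0.3000 C
CHARGE HIS NE2    0.2500 N
CHARGE ILE N     -0.4000 N
CHARGE ILE CA     0.4000 C
CHARGE ILE C      0.6000 C
CHARGE ILE O     -0.6000 O
CHARGE ILE CB     0.0000 C
CHARGE ILE CG1    0.0000 C
CHARGE ILE CG2    0.0000 C
CHARGE ILE CD1    0.0000 C
CHARGE LEU N     -0.4000 N
CHARGE LEU CA     0.4000 C
CHARGE LEU C      0.6000 C
CHARGE LEU O     -0.6000 O
CHARGE LEU CB     0.0000 C
CHARGE LEU CG     0.0000 C
CHARGE LEU CD1    0.0000 C
CHARGE LEU CD2    0.0000 C
CHARGE LYS N     -0.4000 N
CHARGE LYS CA     0.4000 C
CHARGE LYS C      0.6000 C
CHARGE LYS O     -0.6000 O
CHARGE LYS CB     0.0000 C
CHARGE LYS CG     0.0000 C
CHARGE LYS CD     0.0000 C
CHARGE LYS CE     0.3000 C
CHARGE LYS NZ     0.7000 N
CHARGE MET N     -0.4000 N
CHARGE MET CA     0.4000 C
CHARGE MET C      0.6000 C
CHARGE MET O     -0.6000 O
CHARGE MET CB     0.0000 C
CHARGE MET CG     0.1500 C
CHARGE MET SD    -0.3000 S
CHARGE MET CE     0.1500 C
CHARGE PHE N     -0.4000 N
CHARGE PHE CA     0.4000 C
CHARGE PHE C      0.6000 C
CHARGE PHE O     -0.6000 O
CHARGE PHE CB     0.0000 C
CHARGE PHE CG     0.0000 C
CHARGE PHE CD1    0.0000 C
CHARGE PHE CD2    0.0000 C
CHARGE PHE CE1    0.0000 C
CHARGE PHE CE2    0.0000 C
CHARGE PHE CZ     0.0000 C
CHARGE PRO N     -0.4000 N
CHARGE PRO CA     0.4000 C
CHARGE PRO C      0.6000 C
CHARGE PRO O     -0.6000 O
CHARGE PRO CB     0.0000 C
CHARGE PRO CG     0.0000 C
CHARGE PRO CD     0.0000 C
CHARGE SER N     -0.4000 N
CHARGE SER CA     0.4000 C
CHARGE SER C      0.6000 C
CHARGE SER O     -0.6000 O
CHARGE SER CB     0.3000 C
CHARGE SER OG    -0.3000 O
CHARGE THR N     -0.4000 N
CHARGE THR CA     0.4000 C
CHARGE THR C      0.6000 C
CHARGE THR O     -0.6000 O
CHARGE THR CB     0.3000 C
CHARGE THR OG1   -0.3000 O
CHARGE THR CG2    0.0000 C
CHARGE TRP N     -0.4000 N
CHARGE TRP CA     0.4000 C
CHARGE TRP C      0.6000 C
CHARGE TRP O     -0.6000 O
CHARGE TRP CB     0.0000 C
CHARGE TRP CG     0.0000 C
CHARGE TRP CD1    0.1000 C
CHARGE TRP CD2    0.0000 C
CHARGE TRP NE1   -0.3000 N
CHARGE TRP CE2    0.2000 C
CHARGE TRP CE3    0.0000 C
CHARGE TRP CZ2    0.0000 C
CHARGE TRP CZ3    0.0000 C
CHARGE TRP CH2    0.0000 C
CHARGE TYR N     -0.4000 N
CHARGE TYR CA     0.4000 C
CHARGE TYR C      0.6000 C
CHARGE TYR O     -0.6000 O
CHARGE TYR CB     0.0000 C
CHARGE TYR CG     0.0000 C
CHARGE TYR CD1    0.0000 C
CHARGE TYR CD2    0.0000 C
CHARGE TYR CE1    0.0000 C
CHARGE TYR CE2    0.0000 C
CHARGE TYR CZ     0.3500 C
CHARGE TYR OH    -0.3500 O
CHARGE VAL N     -0.4000 N
CHARGE VAL CA     0.4000 C
CHARGE VAL C      0.6000 C
CHARGE VAL O     -0.6000 O
CHARGE VAL CB     0.0000 C
CHARGE VAL CG1    0.0000 C
CHARGE VAL CG2    0.0000 C
CLASS C 3.5000 0.0660 1.9000
CLASS N 3.2500 0.1700 1.7000
CLASS O 2.9600 0.2100 1.5000
CLASS S 3.6000 0.2500 1.9000
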