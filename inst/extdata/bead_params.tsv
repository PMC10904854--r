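# Default per-atom parameter table for switchtile bead and minimal
# backbone heavy-atom representations. Simplified, package-defined
# values (NOT a molecular mechanics force field). Units: Da, e,
# kcal/mol, Angstrom.
residue_name	atom_name	mass	charge	lj_epsilon	lj_rmin_half	gb_radius
ALA	BB	71.0788	0	0.25	2.6	2.6
ARG	BB	156.1875	1	0.1	2.6	2.6
ASN	BB	114.1038	0	0.1	2.6	2.6
ASP	BB	115.0886	-1	0.1	2.6	2.6
CYS	BB	103.1388	0	0.25	2.6	2.6
GLN	BB	128.1307	0	0.1	2.6	2.6
GLU	BB	129.1155	-1	0.1	2.6	2.6
GLY	BB	57.0519	0	0.1	2.6	2.6
HIS	BB	137.1411	0	0.1	2.6	2.6
ILE	BB	113.1594	0	0.25	2.6	2.6
LEU	BB	113.1594	0	0.25	2.6	2.6
LYS	BB	128.1741	1	0.1	2.6	2.6
MET	BB	131.1926	0	0.25	2.6	2.6
PHE	BB	147.1766	0	0.25	2.6	2.6
PRO	BB	97.1167	0	0.1	2.6	2.6
SER	BB	87.0782	0	0.1	2.6	2.6
THR	BB	101.1051	0	0.1	2.6	2.6
TRP	BB	186.2132	0	0.25	2.6	2.6
TYR	BB	163.176	0	0.1	2.6	2.6
VAL	BB	99.1326	0	0.25	2.6	2.6
BED	BB	110	0	0.15	2.6	2.6
LIG	L1	30	0	0.15	1.9	1.9
LIG	L2	30	0	0.15	1.9	1.9
LIG	L3	30	0	0.15	1.9	1.9
LIG	L4	30	0	0.15	1.9	1.9
ALA	N	14.007	-0.4	0.17	1.824	1.55
ALA	CA	12.011	0.1	0.1094	1.908	1.7
ALA	C	12.011	0.55	0.086	1.908	1.7
ALA	O	15.999	-0.5	0.21	1.6612	1.5
ALA	CB	12.011	-0.05	0.1094	1.908	1.7
ARG	N	14.007	-0.4	0.17	1.824	1.55
ARG	CA	12.011	0.1	0.1094	1.908	1.7
ARG	C	12.011	0.55	0.086	1.908	1.7
ARG	O	15.999	-0.5	0.21	1.6612	1.5
ARG	CB	12.011	-0.05	0.1094	1.908	1.7
ASN	N	14.007	-0.4	0.17	1.824	1.55
ASN	CA	12.011	0.1	0.1094	1.908	1.7
ASN	C	12.011	0.55	0.086	1.908	1.7
ASN	O	15.999	-0.5	0.21	1.6612	1.5
ASN	CB	12.011	-0.05	0.1094	1.908	1.7
ASP	N	14.007	-0.4	0.17	1.824	1.55
ASP	CA	12.011	0.1	0.1094	1.908	1.7
ASP	C	12.011	0.55	0.086	1.908	1.7
ASP	O	15.999	-0.5	0.21	1.6612	1.5
ASP	CB	12.011	-0.05	0.1094	1.908	1.7
CYS	N	14.007	-0.4	0.17	1.824	1.55
CYS	CA	12.011	0.1	0.1094	1.908	1.7
CYS	C	12.011	0.55	0.086	1.908	1.7
CYS	O	15.999	-0.5	0.21	1.6612	1.5
CYS	CB	12.011	-0.05	0.1094	1.908	1.7
GLN	N	14.007	-0.4	0.17	1.824	1.55
GLN	CA	12.011	0.1	0.1094	1.908	1.7
GLN	C	12.011	0.55	0.086	1.908	1.7
GLN	O	15.999	-0.5	0.21	1.6612	1.5
GLN	CB	12.011	-0.05	0.1094	1.908	1.7
GLU	N	14.007	-0.4	0.17	1.824	1.55
GLU	CA	12.011	0.1	0.1094	1.908	1.7
GLU	C	12.011	0.55	0.086	1.908	1.7
GLU	O	15.999	-0.5	0.21	1.6612	1.5
GLU	CB	12.011	-0.05	0.1094	1.908	1.7
GLY	N	14.007	-0.4	0.17	1.824	1.55
GLY	CA	12.011	0.1	0.1094	1.908	1.7
GLY	C	12.011	0.55	0.086	1.908	1.7
GLY	O	15.999	-0.5	0.21	1.6612	1.5
HIS	N	14.007	-0.4	0.17	1.824	1.55
HIS	CA	12.011	0.1	0.1094	1.908	1.7
HIS	C	12.011	0.55	0.086	1.908	1.7
HIS	O	15.999	-0.5	0.21	1.6612	1.5
HIS	CB	12.011	-0.05	0.1094	1.908	1.7
ILE	N	14.007	-0.4	0.17	1.824	1.55
ILE	CA	12.011	0.1	0.1094	1.908	1.7
ILE	C	12.011	0.55	0.086	1.908	1.7
ILE	O	15.999	-0.5	0.21	1.6612	1.5
ILE	CB	12.011	-0.05	0.1094	1.908	1.7
LEU	N	14.007	-0.4	0.17	1.824	1.55
LEU	CA	12.011	0.1	0.1094	1.908	1.7
LEU	C	12.011	0.55	0.086	1.908	1.7
LEU	O	15.999	-0.5	0.21	1.6612	1.5
LEU	CB	12.011	-0.05	0.1094	1.908	1.7
LYS	N	14.007	-0.4	0.17	1.824	1.55
LYS	CA	12.011	0.1	0.1094	1.908	1.7
LYS	C	12.011	0.55	0.086	1.908	1.7
LYS	O	15.999	-0.5	0.21	1.6612	1.5
LYS	CB	12.011	-0.05	0.1094	1.908	1.7
MET	N	14.007	-0.4	0.17	1.824	1.55
MET	CA	12.011	0.1	0.1094	1.908	1.7
MET	C	12.011	0.55	0.086	1.908	1.7
MET	O	15.999	-0.5	0.21	1.6612	1.5
MET	CB	12.011	-0.05	0.1094	1.908	1.7
PHE	N	14.007	-0.4	0.17	1.824	1.55
PHE	CA	12.011	0.1	0.1094	1.908	1.7
PHE	C	12.011	0.55	0.086	1.908	1.7
PHE	O	15.999	-0.5	0.21	1.6612	1.5
PHE	CB	12.011	-0.05	0.1094	1.908	1.7
PRO	N	14.007	-0.4	0.17	1.824	1.55
PRO	CA	12.011	0.1	0.1094	1.908	1.7
PRO	C	12.011	0.55	0.086	1.908	1.7
PRO	O	15.999	-0.5	0.21	1.6612	1.5
PRO	CB	12.011	-0.05	0.1094	1.908	1.7
SER	N	14.007	-0.4	0.17	1.824	1.55
SER	CA	12.011	0.1	0.1094	1.908	1.7
SER	C	12.011	0.55	0.086	1.908	1.7
SER	O	15.999	-0.5	0.21	1.6612	1.5
SER	CB	12.011	-0.05	0.1094	1.908	1.7
THR	N	14.007	-0.4	0.17	1.824	1.55
THR	CA	12.011	0.1	0.1094	1.908	1.7
THR	C	12.011	0.55	0.086	1.908	1.7
THR	O	15.999	-0.5	0.21	1.6612	1.5
THR	CB	12.011	-0.05	0.1094	1.908	1.7
TRP	N	14.007	-0.4	0.17	1.824	1.55
TRP	CA	12.011	0.1	0.1094	1.908	1.7
TRP	C	12.011	0.55	0.086	1.908	1.7
TRP	O	15.999	-0.5	0.21	1.6612	1.5
TRP	CB	12.011	-0.05	0.1094	1.908	1.7
TYR	N	14.007	-0.4	0.17	1.824	1.55
TYR	CA	12.011	0.1	0.1094	1.908	1.7
TYR	C	12.011	0.55	0.086	1.908	1.7
TYR	O	15.999	-0.5	0.21	1.6612	1.5
TYR	CB	12.011	-0.05	0.1094	1.908	1.7
VAL	N	14.007	-0.4	0.17	1.824	1.55
VAL	CA	12.011	0.1	0.1094	1.908	1.7
VAL	C	12.011	0.55	0.086	1.908	1.7
VAL	O	15.999	-0.5	0.21	1.6612	1.5
VAL	CB	12.011	-0.05	0.1094	1.908	1.7
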