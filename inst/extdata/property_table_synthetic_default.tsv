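# splicescape default dinucleotide property table -- SYNTHETIC representative values.
# One row per parameter, one column per canonical reverse-complement step class.
# Units: torsions/phase/rotational parameters in degrees, translations in Angstrom,
# energies in kcal/mol. The numbers are hand-assembled to sit in the literature
# range for B-DNA with plausible step-to-step contrast; they are NOT measurements
# from any crystal-structure compilation and carry no provenance beyond this file.
# Replace with a table built from real observations (build_table) for production use.
parameter	AA	AC	AG	AT	CA	CC	CG	GA	GC	TA
Alpha	-62.1	-64.8	-63.5	-65.2	-60.3	-63.9	-61.4	-62.7	-64.5	-60.8
Beta	172.4	169.8	171.1	168.9	175.2	170.4	173.6	171.9	169.3	175.8
Gamma	53.7	56.2	55	56.8	51.4	55.5	52.6	54.2	56.5	51.9
Delta	123.5	119.2	121.4	117.8	128.3	120.6	126.1	122.8	118.5	129
Epsilon	-170.2	-174.5	-172.3	-175.8	-166.4	-173.1	-168.2	-171.5	-175.1	-165.9
Zeta	-103.4	-97.6	-100.5	-95.8	-108.9	-99.1	-106.2	-102.3	-96.7	-109.8
Chi	-114.6	-119.3	-117	-120.8	-110.2	-118.1	-112.4	-115.8	-119.9	-109.5
Phase	152.3	142.6	147.4	139.8	161.5	144.9	157.2	150.1	141.2	163
Amplitude	38.6	41.2	39.9	42	36.4	40.6	37.5	39.1	41.6	36
Shift	-0.03	0.13	0.09	0	0.09	0.05	0	-0.28	0	0
Slide	-0.08	-0.58	-0.25	-0.59	0.53	-0.22	0.41	0.09	-0.38	0.05
Rise	3.27	3.36	3.34	3.31	3.33	3.42	3.39	3.37	3.4	3.42
Tilt	-1.4	-0.1	-1.7	0	0.5	-0.1	0	-1.5	0	0
Roll	0.7	0.7	4.5	1.1	4.7	3.6	5.4	1.9	0.3	3.3
Twist	35.1	31.5	31.9	29.3	37.3	32.9	36.1	36.3	33.6	37.8
H-Rise	3.29	3.33	3.32	3.3	3.36	3.4	3.38	3.35	3.39	3.4
H-Twist	35.8	32.2	32.6	30.5	38.1	33.7	36.9	37	34.4	38.5
Shear	0.01	-0.04	0.02	0	0.03	-0.02	0	-0.05	0	0
Stretch	-0.15	-0.18	-0.16	-0.17	-0.13	-0.19	-0.14	-0.16	-0.2	-0.12
Stagger	0.08	0.12	0.1	0.14	0.04	0.11	0.06	0.09	0.13	0.03
Buckle	0.5	-1.2	0.8	0	2.1	-0.7	0	1.4	0	0
Propel	-17.3	-12.4	-14.1	-15	-9.6	-11.2	-10.1	-13.8	-11.8	-10.5
Opening	1.6	2.3	1.9	1.2	3.1	2	2.6	1.8	1.4	3.4
X-Displacement	-0.55	-1.05	-0.8	-1.1	-0.25	-0.75	-0.35	-0.5	-0.95	-0.3
Y-Displacement	0.02	-0.1	0.05	0	0.08	-0.04	0	-0.12	0	0
Inclination	2.2	4.1	3.3	4.6	1.2	3.5	1.8	2.6	4.3	1.4
Tip	0.4	-0.6	0.2	0	0.9	-0.3	0	0.6	0	0
Axis-Bend	2.9	3.8	3.3	4.2	2.2	3.5	2.5	3	3.9	2.1
Hydrogen-Bond-Energy	-10.3	-12.9	-12.4	-10.8	-12.1	-15.1	-14.6	-11.9	-15.3	-9.9
Stacking-Energy	-5.37	-10.51	-6.78	-6.57	-6.57	-8.26	-9.61	-9.81	-14.59	-3.82
Solvation-Energy	-160.2	-171.5	-166.8	-158.4	-174.3	-185.1	-180.6	-169.9	-188.7	-155
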