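# Standard deoxynucleobase template coordinates, version 1.0
# Coordinates (Angstrom) of the four canonical bases expressed in the
# standard base reference frame (Tsukuba convention): the frame origin lies
# in the base plane near the ring center, x points away from the sugar edge
# into the major-groove direction, y runs along the long axis of the base
# toward the Watson-Crick edge shared by a paired base, and z (x cross y) is
# the base normal.  Complementary bases placed in frames related by a
# 180-degree rotation about x form an ideal Watson-Crick pair.
# The C1' entry anchors the glycosidic attachment of the sugar template.
# Columns: base atom element x y z
base	atom	element	x	y	z
A	C1'	C	-2.479	5.346	0.000
A	N9	N	-1.291	4.498	0.000
A	C8	C	0.024	4.897	0.000
A	N7	N	0.877	3.902	0.000
A	C5	C	0.071	2.771	0.000
A	C6	C	0.369	1.398	0.000
A	N6	N	1.611	0.909	0.000
A	N1	N	-0.668	0.532	0.000
A	C2	C	-1.912	1.023	0.000
A	N3	N	-2.320	2.290	0.000
A	C4	C	-1.267	3.124	0.000
G	C1'	C	-2.477	5.399	0.000
G	N9	N	-1.289	4.551	0.000
G	C8	C	0.023	4.962	0.000
G	N7	N	0.870	3.969	0.000
G	C5	C	0.071	2.833	0.000
G	C6	C	0.424	1.460	0.000
G	O6	O	1.554	0.955	0.000
G	N1	N	-0.700	0.641	0.000
G	C2	C	-1.999	1.087	0.000
G	N2	N	-2.949	0.139	-0.001
G	N3	N	-2.342	2.364	0.001
G	C4	C	-1.265	3.177	0.000
C	C1'	C	-2.477	5.402	0.000
C	N1	N	-1.285	4.542	0.000
C	C2	C	-1.472	3.158	0.000
C	O2	O	-2.628	2.709	0.001
C	N3	N	-0.391	2.344	0.000
C	C4	C	0.837	2.868	0.000
C	N4	N	1.875	2.027	0.001
C	C5	C	1.056	4.275	0.000
C	C6	C	-0.023	5.068	0.000
T	C1'	C	-2.481	5.354	0.000
T	N1	N	-1.284	4.500	0.000
T	C2	C	-1.462	3.135	0.000
T	O2	O	-2.562	2.608	0.000
T	N3	N	-0.298	2.407	0.000
T	C4	C	0.994	2.897	0.000
T	O4	O	1.944	2.119	0.000
T	C5	C	1.106	4.338	0.000
T	C7	C	2.466	4.961	0.001
T	C6	C	-0.024	5.057	0.000
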