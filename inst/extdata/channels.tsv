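# Default reaction-channel library for triterpenoid synthases.
# One record per carbocationic intermediate, tab-separated:
#   id        "<channel>-I<index>"
#   channel   A (hopene), B (lupeol/dammarenyl), C (lanosterol/protosteryl),
#             D (sesquarterpenoid C35; present but disabled for ranking)
#   index     1-based position along the channel
#   rep       representative rank used by hierarchical ranking (1, 2, or -)
#   chem_id   chemical identity; A-I1 and B-I1 are the same cation in
#             different active-site folds, so they share a chem_id
#   conformer free-text conformer / fold note
#   products  products quenched from this cation, "name:EC|name:EC" ("-" none;
#             EC may be empty)
id	channel	index	rep	chem_id	conformer	products
A-I1	A	1	1	I1-6,6-bicyclic	all-chair fold	gamma-polypodatetraene:
A-I2	A	2	2	A-I2	6,6,6,5-tetracyclic	tetracyclic-byproducts:
A-I3	A	3	-	A-I3	6,6,6,6-tetracyclic, bridged	-
A-I4	A	4	-	A-I4	hopanyl cation, pentacyclic	hopene:5.4.99.17|hopan-22-ol:
B-I1	B	1	1	I1-6,6-bicyclic	all-chair fold, dammarenyl-type	-
B-I2	B	2	2	B-I2	dammarenyl-type 6,6,6,5-tetracyclic	dammara-20,24-diene:
C-I1	C	1	1	C-I1	chair-boat-chair fold	-
C-I2	C	2	2	C-I2	protosteryl-type 6,6,6,5-tetracyclic	-
C-I3	C	3	-	C-I3	6,6,6,6-tetracyclic	-
C-I4	C	4	-	C-I4	protosteryl cation	protostadienol:
C-I5	C	5	-	C-I5	hydride-shift intermediate	-
C-I6	C	6	-	C-I6	lanosteryl-region cation	lanosterol:5.4.99.7
C-I7	C	7	-	C-I7	also a lanosterol precursor	parkeol:
C-I8	C	8	-	C-I8	cycloartenol precursor	cycloartenol:5.4.99.8
C-I9	C	9	-	C-I9	cucurbitadienol precursor	cucurbitadienol:5.4.99.33
D-I1	D	1	1	D-I1	C35 bicyclic	-
D-I2	D	2	2	D-I2	C35 polycyclic	-
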