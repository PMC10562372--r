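COX1	cox1
COI	cox1
CO1	cox1
COXI	cox1
COX-1	cox1
CYTOCHROME C OXIDASE SUBUNIT I	cox1
CYTOCHROME C OXIDASE SUBUNIT 1	cox1
COX2	cox2
COII	cox2
CO2	cox2
COXII	cox2
CYTOCHROME C OXIDASE SUBUNIT II	cox2
CYTOCHROME C OXIDASE SUBUNIT 2	cox2
COX3	cox3
COIII	cox3
CO3	cox3
COXIII	cox3
CYTOCHROME C OXIDASE SUBUNIT III	cox3
CYTOCHROME C OXIDASE SUBUNIT 3	cox3
CYTB	cytb
COB	cytb
CYB	cytb
CYT B	cytb
CYTOCHROME B	cytb
ATP6	atp6
ATPASE6	atp6
ATPASE 6	atp6
ATP SYNTHASE F0 SUBUNIT 6	atp6
ATP8	atp8
ATPASE8	atp8
ATPASE 8	atp8
ATP SYNTHASE F0 SUBUNIT 8	atp8
NAD4L	nad4l
ND4L	nad4l
NADH4L	nad4l
NADH DEHYDROGENASE SUBUNIT 4L	nad4l
NAD1	nad1
ND1	nad1
NADH1	nad1
NADH DEHYDROGENASE SUBUNIT 1	nad1
NAD2	nad2
ND2	nad2
NADH2	nad2
NADH DEHYDROGENASE SUBUNIT 2	nad2
NAD3	nad3
ND3	nad3
NADH3	nad3
NADH DEHYDROGENASE SUBUNIT 3	nad3
NAD4	nad4
ND4	nad4
NADH4	nad4
NADH DEHYDROGENASE SUBUNIT 4	nad4
NAD5	nad5
ND5	nad5
NADH5	nad5
NADH DEHYDROGENASE SUBUNIT 5	nad5
NAD6	nad6
ND6	nad6
NADH6	nad6
NADH DEHYDROGENASE SUBUNIT 6	nad6
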