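gene	part	sequence
DLAT	probe	56-FAM/CGCTGTGCA/ZEN/ATAACCCGACGAATG/3IABkFQ
DLAT	primer1	CCAGTTCCTACAGGTGTCTTC
DLAT	primer2	TGAGGTATGGTTTGCTTTGATTG
HLADPB1	probe	56-FAM/CCCACTCCA/ZEN/CAGATGATGAGCCC/3IABkFQ
HLADPB1	primer1	GCTCCTCCTGTGCATGAAG
HLADPB1	primer2	CAAGTGGAGCACACCAG
MFN1	probe	56-FAM/AGCTTCTAC/ZEN/TCCCACTGCTCCTACC/3IABkFQ
MFN1	primer1	GAAATGCTCAAAGGGTGCTC
MFN1	primer2	GTGATGCATTATCTGGCGTTG
MT1X	probe	56-FAM/AGCTCGCCA/ZEN/TGGATCCCAACT/3IABkFQ
MT1X	primer1	GCAACCTGTCCCGACTCTA
MT1X	primer2	AGCTTTTCTTGCAGGAGGTG
NDUFAF4	probe	56-FAM/CTGTGTCTT/ZEN/CCTTGCAGGTAAAAGCTG/3IABkFQ
NDUFAF4	primer1	CCAGAAGTTAAAGGAGAGATTGCT
NDUFAF4	primer2	GAATTCCTTCGGCTCTTGAC
SUCLG2	probe	56-FAM/CACAGCTGA/ZEN/TCCTAAGGTTGAAGCCA/3IABkFQ
SUCLG2	primer1	TTGGAGGTGGTGTAAAGGAAG
SUCLG2	primer2	GGCAATGATGGCACAGTTG
ACTB	probe	56-FAM/CTGCCTCCA/ZEN/CCCACTCCCA/3IABkFQ
ACTB	primer1	GTCCCCCAACTTGAGATGTATG
ACTB	primer2	AAGTCAGTGTACAGGTAAGCC
GAPDH	probe	56-FAM/AAGGTCGGA/ZEN/GTCAACGGATTTGGTC/3IABkFQ
GAPDH	primer1	ACATCGCTCAGACACCATG
GAPDH	primer2	TGTAGTTGAGGTCAATGAAGGG
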