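# Published consensus set of 42 housekeeping transcripts for human
# kidney allograft biopsy RNA-seq, common to all nine normalization
# methods. One symbol per line; PMF1/PMF1-BGLAP is a readthrough locus
# reported as a single transcript entry.
ANAPC5
ANAPC15
ARID3B
ARL10
ATXN2
C16orf62
C3orf49
CCAR1
CCDC125
CCDC90B
CHFR
DHRSX
FRMD8
GGA1
HERC4
MKNK1
NASP
NME4
OTUB1
PMF1/PMF1-BGLAP
POLR2B
POLR3A
POMK
PSMA3-AS1
PTPN14
RAPGEF6
REL
RRP1
RUNDC1
SAMD4B
SLC4A1AP
SLMAP
SMARCAL1
SNAP29
SNRNP200
SUPT4H1
TBC1D22A
THUMPD3-AS1
TSPOAP1-AS1
TUBGCP2
WDTC1
ZNF544
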