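locus	repeats
DYS19	16
DYS389I	13
DYS389b	16
DYS390	25
DYS391	10
DYS392	11
DYS393	13
DYS437	14
DYS438	10
DYS439	10
DYS448	22
DYS456	15
DYS458	18
DYS635	21
GATA_H4	11
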