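>SpOpB_synthetic synthetic stand-in reference for S. proteamaculans oligopeptidase B (685 aa; documented residues planted at author positions)
MASHHHHHHACSSNFPRLEITGYVPPFQLNDNRKKNVSDQLDPGFGQQMQGMASANQAPK
GAKCKQSVPRIPQQEHMMTPHQPVSSKGINLEVKNEYRVYDLHRGNQDTLSLMKHLRQDR
ATDREMYAKRMAAIMNPNWLLSEYADQLSRRAKDQKRMPQLQTLLAHAGRIMREFVYQLF
FSDCPLLDAEKKEKNLRSFLTIQLHAMSLSRYGLLDLKLVADILPAIPTPDVFLKRREGG
LQETDKPDSPQTVNPDQLNVPGVALHSFLEDREHRIDGDLNGNYVDITQIKNAGKIKMQS
SGVPSLSNYAGDSDDPMHSLDNPTDSGAMLDSRMIGRLITRGATSDVRNGACEKVPDATV
TDVYNPISLRSVYQDNVTTSLMCSAVEDILFEEIYNLDNIECDIALKNGTEENSGSMRFK
VEFGAGAKRQMLLVFYVVLNTLFILETKLFRYSLYIQSEDPSFDMANVNATRRGPAAIVQ
GSLADPELDQLLVELSLDRTYELQTEDFELEIAGYTALNASRKTENLRPTRSASELAAAL
VHVIGVFQFMGAPTPVGFVGEVITMNVKLKQDNTGETDDLPGQKTSKWHMIELQTQLDMG
GCRDEGGIMILVTQLHDSQVQFGFITRCLIDIWMEGSNKFCFSNYGTMDSGHGQKSARFK
RYEDAENAPLEINFRFNLKKRKVSE
>TbOpB_synthetic synthetic stand-in reference for T. brucei oligopeptidase B (716 aa; +21/+31 numbering offsets, anchors E172/R650)
MASHHHHHHTCSDRFARLECGGYVPWAKLNDNRRKNISMQLDPGFGTQMQGGASANQAPK
GFGCKQEVARIPQQEHAMTPHEPTSSNGIVLEWKNEYYVPIFVPKGIGLTSPIVAQNRKE
IDIHAGNQDTLSLMPHLTQQRAPDREMYAKKMAQIHKPNMNEYEYADQWSTEADSQKRMT
QLQTQLKHIGRIMREFICQLFFADCFHYDTECKEKNLVSFLNIQLHAESESKYGVFDCSL
VLDALPAIIKPTLFLKRGPQSLQETQKPDSPATVNQDQLNAPGVVIHSYLHSPEASKDGI
LNPRYVCITCIKNFGKPDMQEKGCEKHDAPTSGKPSHENYAGDDDDEMHSWDNPHDGDGM
LDSRARGRLDPWGATSKMRQGFHWKVPDATVTDVYNPISLASELQDVVVMSLMCGAKEDI
LQEEIYALCNKECITALKNLTHENSGSIRFKVYDCAAFMRQRLLAFFVVTNTLLICEDKH
FRYSYYNQSKDPSFAMWRVNATRRGPAAIVQGLICDPELDQLLVELSLMRFYQEQNEDIE
LMISGYTDLNASRKTRELRPTKSAMKLAAVKVAVHGVFQRMGAPTFVGFVGEPITMKVWL
KQDNTGETDDLITQKTSKQHMAELQTALHMGGCSFEGGIMWGGAQLHDARVQYQFIKRCL
IIDVMEYSGWFMFSNYGTMDSGHGGKSGRFKRYEDFENIPLEITTRFNLQERFCSE
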