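LOCUS       SYNTEST                   84 bp    DNA     linear   SYN 01-JAN-2026
DEFINITION  Synthetic miniature genome for CDS-extraction tests (not a real
            organism).
ACCESSION   SYNTEST01
FEATURES             Location/Qualifiers
     source          1..84
                     /organism="synthetic construct"
     CDS             1..18
                     /locus_tag="SYN_0001"
                     /gene="synA"
     tRNA            19..48
                     /locus_tag="SYN_t001"
                     /product="tRNA-Xxx"
     CDS             complement(49..66)
                     /locus_tag="SYN_0002"
                     /gene="synB"
     CDS             join(67..75,76..84)
                     /locus_tag="SYN_0003"
                     /gene="synC"
ORIGIN
        1 atggctaaag gctcctaaac gtacgtacgt acgtacgtac gtacgtactt aggtaaaccc
       61 gggcatatgg atcgatcttg gtaa
//
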