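LOCUS       toy 120 bp    DNA     circular PLN 01-JAN-2026
DEFINITION  toy.
ACCESSION   toy
FEATURES             Location/Qualifiers
     source          1..120
     gene            complement(11..40)
                     /gene="rpl2"
     gene            51..80
                     /gene="psbA"
     tRNA            91..110
                     /gene="trnH"
ORIGIN
        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
       61 tgcatgcatg catgcatgca tgcatgcatg catgcatgca tgcatgcatg catgcatgca
//
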