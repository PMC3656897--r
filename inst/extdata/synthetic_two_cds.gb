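LOCUS       SYN0001                 12000 bp    DNA     linear   SYN 01-JAN-2026
DEFINITION  Synthetic two-CDS fixture for flat-file CDS translation parsing.
ACCESSION   SYN0001
VERSION     SYN0001.1
SOURCE      synthetic construct
FEATURES             Location/Qualifiers
     source          1..2000
                     /organism="synthetic construct"
     CDS             1..180
                     /gene="synA"
                     /locus_tag="SYN_0001"
                     /translation="MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGT
                     QDNLSGAEKAVQ"
     CDS             301..450
                     /gene="synB"
                     /translation="MNITEMLKEAGVSRSTFYRHFKD"
     CDS             601..720
                     /note="translation intentionally absent"
ORIGIN
//
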