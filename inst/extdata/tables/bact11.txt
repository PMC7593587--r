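# gcescan genetic-code table (bact11)
name: bact11
starts: ATG GTG TTG
stops: TAA TAG TGA
readthrough: 
TTT F
CTT L
ATT I
GTT V
TCT S
CCT P
ACT T
GCT A
TAT Y
CAT H
AAT N
GAT D
TGT C
CGT R
AGT S
GGT G
TTC F
CTC L
ATC I
GTC V
TCC S
CCC P
ACC T
GCC A
TAC Y
CAC H
AAC N
GAC D
TGC C
CGC R
AGC S
GGC G
TTA L
CTA L
ATA I
GTA V
TCA S
CCA P
ACA T
GCA A
TAA *
CAA Q
AAA K
GAA E
TGA *
CGA R
AGA R
GGA G
TTG L
CTG L
ATG M
GTG V
TCG S
CCG P
ACG T
GCG A
TAG *
CAG Q
AAG K
GAG E
TGG W
CGG R
AGG R
GGG G
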