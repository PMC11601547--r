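>query_A
MKVLA
>seq1 some description
MKALa-
>seq2
mMRVLA
>seq3
MK-LA
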