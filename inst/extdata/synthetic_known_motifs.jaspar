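# Synthetic known-motif library (JASPAR-style counts). These matrices are
# constructed from community consensus sites for testing and best-match
# annotation; they are NOT measured matrices from any database release.
>SYN0001 TCF7L2
A [  2  2  2  2  2 47 47 ]
C [ 94  2  2  2  2  2  2 ]
G [  2  2  2  2 94  2  2 ]
T [  2 94 94 94  2 49 49 ]
>SYN0002 LEF1
A [  2  2  2  2  2  4  2 ]
C [ 90  4  2  2  2  2  2 ]
G [  4  2  2  2 94  2  4 ]
T [  4 92 94 94  2 92 92 ]
>SYN0003 FOXH1
A [ 92 92  2  2  2 92  2 92 ]
C [  2  2  2 92 92  2 92  2 ]
G [  4  2  2  2  2  4  2  4 ]
T [  2  4 94  4  4  2  4  2 ]
>SYN0004 SOX3
A [ 90  2 90 90  2  4 ]
C [  4 90  4  2  2  2 ]
G [  2  4  2  4  2 90 ]
T [  4  4  4  4 94  4 ]
>SYN0005 GATA1
A [ 90  2 90  2 90 90 ]
C [  4  2  4  2  4  4 ]
G [  2 92  2  2  2  2 ]
T [  4  4  4 94  4  4 ]
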