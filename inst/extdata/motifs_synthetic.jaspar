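>SYN_FOXO3 FOXO3
A [  4 12 12 12  0 12 ]
C [  0  0  0  0  6  0 ]
G [  4  0  0  0  0  0 ]
T [  4  0  0  0  6  0 ]
>SYN_SP1 SP1
A [  0  0  0  0  0  0  0  0  0  0  0 ]
C [  0 12 12 12 12  0 12 12 12 12 12 ]
G [ 12  0  0  0  0  6  0  0  0  0  0 ]
T [  0  0  0  0  0  6  0  0  0  0  0 ]
>SYN_MZF1 MZF1
A [  0  0  0  0  0 12 ]
C [  4  0  0  0  0  0 ]
G [  4 12 12 12 12  0 ]
T [  4  0  0  0  0  0 ]
>SYN_THAP1 THAP1
A [  0  0  0  0  0  0  4  0 12 ]
C [  6  0  0 12 12 12  0  4  0 ]
G [  0  0 12  0  0  0  4  4  0 ]
T [  6 12  0  0  0  0  4  4  0 ]
>SYN_KLF16 KLF16
A [  0  6  0 12  0  0  0  0  0  0  0 ]
C [  0  6 12  0 12  0 12 12 12 12 12 ]
G [ 12  0  0  0  0 12  0  0  0  0  0 ]
T [  0  0  0  0  0  0  0  0  0  0  0 ]
>SYN_CTCFL CTCFL
A [  0  6  0  0 12  0  0  0  0  0  0  6  0  0 ]
C [ 12  0  6 12  0  0  0  0  0  0 12  0  6  4 ]
G [  0  6  6  0  0 12 12 12 12 12  0  6  6  4 ]
T [  0  0  0  0  0  0  0  0  0  0  0  0  0  4 ]
>SYN_NEUROD1 NEUROD1
A [  3  6 12  0 12  0 12  0  0  0  0  3  3 ]
C [  3  0  0 12  0  0  0  0  0  0  6  3  3 ]
G [  3  6  0  0  0 12  0  0 12 12  0  3  3 ]
T [  3  0  0  0  0  0  0 12  0  0  6  3  3 ]
>SYN_TFAP2A TFAP2A
A [  4  0  0  0  0  0 12  0  0  0  4 ]
C [  4  0 12 12  6  6  0  0  0 12  0 ]
G [  0 12  0  0  0  6  0 12 12  0  4 ]
T [  4  0  0  0  6  0  0  0  0  0  4 ]
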