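>CTCF_like synthetic
A [   5   5  85   5   5  85   5   5   5   5   5   5   5   5 ]
C [  85  85   5  85  85   5   5   5   5   5   5  85   5  85 ]
G [   5   5   5   5   5   5  85  85  85  85  85   5  85   5 ]
T [   5   5   5   5   5   5   5   5   5   5   5   5   5   5 ]
>ERE_like synthetic
A [   5   5   5   5  85  25  25  25   5   5  85   5   5 ]
C [   5   5   5  85   5  25  25  25   5   5   5  85  85 ]
G [  85  85   5   5   5  25  25  25   5  85   5   5   5 ]
T [   5   5  85   5   5  25  25  25  85   5   5   5   5 ]
>FOXA1_like synthetic
A [   5   5   5   5   5  85   5  85 ]
C [   5   5   5   5   5   5  85   5 ]
G [   5  85   5   5   5   5   5   5 ]
T [  85   5  85  85  85   5   5   5 ]
>MYF_like synthetic
A [   5  85   5   5   5   5 ]
C [  85   5   5  85   5   5 ]
G [   5   5  85   5   5  85 ]
T [   5   5   5   5  85   5 ]
>AP1_like synthetic
A [   5   5  85   5   5   5  85 ]
C [   5   5   5  85   5  85   5 ]
G [   5  85   5   5   5   5   5 ]
T [  85   5   5   5  85   5   5 ]
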