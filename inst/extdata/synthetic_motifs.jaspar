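>MSYN01 synthetic_hox_like
A  [ 1 1 97 1 1 97 97 1 ]
C  [ 1 1 1 1 1 1 1 1 ]
G  [ 1 97 1 1 1 1 1 1 ]
T  [ 97 1 1 97 97 1 1 97 ]
>MSYN02 synthetic_ebox
A  [ 1 97 1 1 1 1 97 1 ]
C  [ 97 1 97 1 1 1 1 97 ]
G  [ 1 1 1 97 1 97 1 1 ]
T  [ 1 1 1 1 97 1 1 1 ]
>MSYN03 synthetic_nfat_like
A  [ 1 1 1 97 1 1 1 1 1 ]
C  [ 1 1 1 1 1 1 1 97 97 ]
G  [ 97 97 97 1 1 1 1 1 1 ]
T  [ 1 1 1 1 97 97 97 1 1 ]
>MSYN04 synthetic_gata_like
A  [ 97 1 97 1 97 97 1 97 ]
C  [ 1 1 1 1 1 1 1 1 ]
G  [ 1 97 1 1 1 1 97 1 ]
T  [ 1 1 1 97 1 1 1 1 ]
>MSYN05 synthetic_ets_like
A  [ 1 1 1 1 1 1 97 97 1 1 ]
C  [ 1 1 97 97 1 1 1 1 1 1 ]
G  [ 1 1 1 1 97 97 1 1 97 1 ]
T  [ 97 97 1 1 1 1 1 1 1 97 ]
>MSYN06 synthetic_bhlh_like
A  [ 1 97 1 1 1 1 1 1 1 97 ]
C  [ 97 1 1 97 1 1 1 1 97 1 ]
G  [ 1 1 97 1 1 97 1 1 1 1 ]
T  [ 1 1 1 1 97 1 97 97 1 1 ]
>MSYN07 synthetic_tale_like
A  [ 1 1 97 1 97 1 1 1 ]
C  [ 1 1 1 97 1 1 1 1 ]
G  [ 1 97 1 1 1 97 97 1 ]
T  [ 97 1 1 1 1 1 1 97 ]
>MSYN08 synthetic_zinc_finger
A  [ 97 1 1 1 1 97 1 1 1 97 ]
C  [ 1 1 97 1 97 1 1 97 1 1 ]
G  [ 1 1 1 97 1 1 1 1 97 1 ]
T  [ 1 97 1 1 1 1 97 1 1 1 ]
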