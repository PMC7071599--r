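>SYN0001.1 SYNRUNT
A  [  2 95  1  3 80  4 88 90 ]
C  [ 90  1  2  3  5  2  4  3 ]
G  [  4  2 95  2 10 90  4  3 ]
T  [  4  2  2 92  5  4  4  4 ]
>SYN0002.1 SYNEBOX
A  [  5  2 88  2  3  4 ]
C  [ 85  6  4  2  3  5 ]
G  [  5  4  4 90  4  6 ]
T  [  5 88  4  6 90 85 ]
>SYN0003.1 SYNZIP
A  [ 80  5  5 80  5  5 80  5  5 ]
C  [  5 80  5  5 80  5  5 80  5 ]
G  [ 10 10 80 10 10 80 10 10 80 ]
T  [  5  5 10  5  5 10  5  5 10 ]
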