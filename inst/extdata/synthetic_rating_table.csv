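sequence,observed
OOOOOXOO,0.157
OOOOXOXO,0.444
OOOXOOOO,0.121
OOOXOXXO,0.887
OOOXXXOO,0.484
OOXOOOXO,0.462
OOXOXOOO,0.45
OOXOXXXO,0.79
OOXXOXOO,0.87
OOXXXOXO,0.713
OXOOOOOO,0.164
OXOOOXXO,0.899
OXOOXXOO,0.878
OXOXOOXO,0.384
OXOXXOOO,0.904
OXOXXXXO,0.1
OXXOOXOO,0.891
OXXOXOXO,0.264
OXXXOOOO,0.531
OXXXOXXO,0.051
OXXXXXOO,0.112
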