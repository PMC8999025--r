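# non-isomorphic simple undirected graphs on 1..6 nodes
# format: n<TAB>upper-triangle bits (row-major, pairs (1,2),(1,3),...,(n-1,n))
1	
2	0
2	1
3	000
3	100
3	110
3	111
4	000000
4	100000
4	110000
4	111000
4	110100
4	001100
4	101100
4	111100
4	011110
4	111110
4	111111
5	0000000000
5	1000000000
5	1100000000
5	1110000000
5	1111000000
5	1100100000
5	0010100000
5	1010100000
5	1110100000
5	0011100000
5	1011100000
5	1111100000
5	0110110000
5	1110110000
5	0101110000
5	1101110000
5	0111110000
5	1111110000
5	0111111000
5	1111111000
5	1110110100
5	0001110100
5	1001110100
5	1101110100
5	1111110100
5	1111001100
5	0011101100
5	1011101100
5	1111101100
5	0111111100
5	1111111100
5	1111011110
5	1111111110
5	1111111111
6	000000000000000
6	100000000000000
6	110000000000000
6	111000000000000
6	111100000000000
6	111110000000000
6	110001000000000
6	001001000000000
6	101001000000000
6	111001000000000
6	001101000000000
6	101101000000000
6	111101000000000
6	001111000000000
6	101111000000000
6	111111000000000
6	011001100000000
6	111001100000000
6	010101100000000
6	110101100000000
6	011101100000000
6	111101100000000
6	000111100000000
6	100111100000000
6	010111100000000
6	110111100000000
6	011111100000000
6	111111100000000
6	011101110000000
6	111101110000000
6	011011110000000
6	111011110000000
6	011111110000000
6	111111110000000
6	011111111000000
6	111111111000000
6	111001100100000
6	000101100100000
6	100101100100000
6	110101100100000
6	111101100100000
6	000111100100000
6	100111100100000
6	110111100100000
6	111111100100000
6	111100010100000
6	000010010100000
6	100010010100000
6	110010010100000
6	011010010100000
6	111010010100000
6	111110010100000
6	001101010100000
6	101101010100000
6	111101010100000
6	110011010100000
6	001011010100000
6	101011010100000
6	011011010100000
6	111011010100000
6	001111010100000
6	101111010100000
6	111111010100000
6	011101110100000
6	111101110100000
6	011011110100000
6	111011110100000
6	000111110100000
6	100111110100000
6	010111110100000
6	110111110100000
6	011111110100000
6	111111110100000
6	000110011100000
6	100110011100000
6	010110011100000
6	110110011100000
6	011110011100000
6	111110011100000
6	010111011100000
6	110111011100000
6	001111011100000
6	101111011100000
6	011111011100000
6	111111011100000
6	011111111100000
6	111111111100000
6	111100110110000
6	101010110110000
6	111010110110000
6	111110110110000
6	111101110110000
6	001011110110000
6	101011110110000
6	111011110110000
6	001111110110000
6	101111110110000
6	111111110110000
6	000110101110000
6	100110101110000
6	110110101110000
6	001110101110000
6	101110101110000
6	111110101110000
6	110111101110000
6	001111101110000
6	101111101110000
6	111111101110000
6	001110111110000
6	101110111110000
6	011110111110000
6	111110111110000
6	011111111110000
6	111111111110000
6	001110111111000
6	101110111111000
6	111110111111000
6	111111111111000
6	111101110110100
6	000011110110100
6	100011110110100
6	110011110110100
6	111011110110100
6	111111110110100
6	100010001110100
6	110010001110100
6	111010001110100
6	111110001110100
6	101011001110100
6	111011001110100
6	001111001110100
6	101111001110100
6	011111001110100
6	111111001110100
6	111011101110100
6	010111101110100
6	110111101110100
6	011111101110100
6	111111101110100
6	011111111110100
6	111111111110100
6	011111111001100
6	111111111001100
6	111110011101100
6	001111011101100
6	101111011101100
6	111111011101100
6	011111111101100
6	111111111101100
6	101110111111100
6	111110111111100
6	111111111111100
6	011111111011110
6	111111111011110
6	111111111111110
6	111111111111111
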