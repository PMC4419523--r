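00111101011000101011100011001100 i
11011010101100111001110011001000 a
01101101011001101011100011001100 i
00101101001000101011100011001100 i
11010010100100111101110000001000 a
11010010100100011001110011001000 a
11110011001011001110011100110000 u
11010010100100111001110001001000 a
00111101011001101101100011001100 i
11010010100100111001110000001000 a
00101101011110101011100011001100 i
10101100011000111010100001001100 i
01100111001011100110011100110000 u
00101111011000101011100011001100 i
11111010110100111010110011001000 a
00101100011000101001100000001100 i
11100011001011010111011100110000 u
00101101010000101011000011001100 i
00101101011100101011100011011000 i
11011010100100111101110010001000 a
11100011001011000110011100111000 u
00101101111000101011100011001100 i
10010010000100111001111011001000 a
11010010100100100001110011000000 a
11110111001011101110011100100000 u
10100011001011000110011100110000 u
11100011001011000110001100110000 u
00101101011000101011100110001100 i
00101101011000101011100011001100 i
11010010100000111001110011010001 a
10010010100100111001110001001000 a
11010110100100111001010011001000 a
11010000100101111001110111001000 a
11100011001011000110011100110000 u
11100010001011001110111100110000 u
11100011001011100110011100100000 u
00101101011000101011110011001000 i
10010010100100111001110011001010 a
00101101010000101011100011001101 i
00101101011000101011000011001100 i
11000011001011000110011100110000 u
00101101011000001011100001001100 i
00101101001000101011100010001100 i
01100011001010000110011100110000 u
11010010100100111001110010001000 a
11010000100100011101110011001000 a
11110011001011010110011100110000 u
00101101011000101011100011101110 i
11100001001011000110011000110000 u
11100010001011000110011111110000 u
11010010110100111001110011001000 a
11100011011011000110011000110000 u
11100011001011001110011100110000 u
00101101011000101011100010001100 i
11110011001011000110011110110000 u
11010011110110111001100011011000 a
11100111001011000110011100111000 u
11100011001011000010011100110010 u
11000010100100110001110011001100 a
00101101011000101011101111001100 i
00101101011000101011100011001000 i
10100010101011000110011100110000 u
10010010100110111001110011001000 a
11010010100100111001110011001000 a
11010010100100111001100011001000 a
11100011011011000110011100110000 u
11010010100100110001110011001010 a
00101101010000101011100011001100 i
01100111001011000110011100110000 u
00101100011001101011100011011100 i
00101101011010101011100011011100 i
11010111100100111001110010001000 a
10010010100100111001110011000000 a
11010000100100111001010011001010 a
00101101011000101011100011011100 i
11010000100100111101110011001000 a
11100011000011000110011100110000 u
11100001001111000110011100110000 u
11100011001011100010011100110000 u
00101111011000101111100011001100 i
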