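1 2 3 4 5 6 7 8 9 10 11 12 13 20 21 22 23 24 25 26 27 28 29 30 43 44 45 46 47 49 50 51 52 53 54 55 56 57 58 59 60 61 62 63 64 65 66 67 68 69 70 71 72 73 74 75 76 77 78 79 80 81 82 83 84 93 94 95 96 97 98 99 100 101 103 104 105 106 107 108 109 110 111 129 130 131 132 133 134 136 137 138 139 140 141 142 143 144 145 146 147 148 149
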