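3 4 5 6 7 8 9 10 11 12 13 14 16 17 18 19 20 21 22 23 24 25 26 27 30 31 32 33 34 35 36 37 38 44 45 46 47 48 49 50 51 52 53 62 63 64 65 66 82 83 84 85 86 87 88 89 91 92 93 94 95 96 107 108 109 110 111 112 113 114 115 119 120 121 122 123 124 125 133 134 135 136 137 138 139 140 141 142 143 144 145 146 147 148 149
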