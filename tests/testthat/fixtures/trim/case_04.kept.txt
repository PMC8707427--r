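9 10 11 12 13 16 17 18 19 20 21 22 23 24 25 26 27 28 29 30 31 32 33 34 35 48 49 50 51 52 53 55 56 57 58 59 60 61 62 63 64 65 66 67 68 69 70 71 72 73 74 75 76 78 79 80 81 82 83 87 88 89 90 91 92 93 94 95 96 104 105 106 107 108 111 112 113 114 115 116 117 118 119 120 121 122 123 124 131 132 133 134 135 136 137 138 139 140 141 142 143 146 147 148 149 150 155 156 157 158 159 160 163 164 165 166 167 168 169 170
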