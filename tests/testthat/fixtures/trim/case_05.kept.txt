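1 2 3 4 5 6 7 8 9 10 11 12 13 14 15 16 17 18 19 20 21 22 27 28 29 30 31 32 34 35 36 37 38 39 40 41 42 43 51 52 53 54 55 56 57 58 59 60 61 62 63 64 65 66 67 68 70 71 72 73 74 75 76 77 78 79 80 81 82 83 84 85 86 87 88 89 90 91 92 93 94 95 96 97 98 99 100 101 102 103 104 105 106 121 122 123 124 125 126 127 128 129 130 131 132 133 134 135 136 137 138 145 146 147 148 149 150 151 152 153 154 155 163 164 165 166 167 168 170 171 172 173 174 175 176 177 178
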