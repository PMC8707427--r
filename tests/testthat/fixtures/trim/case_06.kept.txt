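3 4 5 6 7 14 15 16 17 18 19 20 21 22 23 24 25 33 34 35 36 37 38 45 46 47 48 49 50 51 52 53 54 55 63 64 65 66 67 68 69 70 71 72 73 74 75 76 77 78 79 80 81 82 96 97 98 99 100 108 109 110 111 112 113 114 115 116 121 122 123 124 125 126 127 129 130 131 132 133 143 144 145 146 147 153 154 155 156 157 158 159 160 161 163 164 165 166 167 168 169 170 171 172 173 174 175 176 177 178 179 182 183 184 185 186 187 188 189
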