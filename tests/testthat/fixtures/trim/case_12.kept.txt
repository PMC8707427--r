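19 20 21 22 23 24 25 26 27 28 31 32 33 34 35 36 37 38 39 40 45 46 47 48 49 50 51 52 53 54 55 56 61 62 63 64 65 66 67 68 69 70 74 75 76 77 78 79 80 81 82 83 84 88 89 90 91 92 93 94 95 96 97 98 99 100 101 102 108 109 110 111 112 113 114 117 118 119 120 121 122 123 124 138 139 140 141 142 143 144 145 146 147 148 152 153 154 155 156 157 158 159 160
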