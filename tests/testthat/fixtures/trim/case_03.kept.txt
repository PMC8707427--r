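2 3 4 5 6 7 8 9 10 11 12 13 14 15 27 28 29 30 31 32 33 34 35 36 37 38 39 40 41 42 43 44 45 46 47 48 59 60 61 62 63 64 65 66 67 68 69 70 71 72 73 74 75 76 77 78 81 82 83 84 85 86 87 88 89 90 93 94 95 96 97 98 102 103 104 105 106 107 108 109 110 111 112 113 114 115 116 117 119 120 121 122 123 124 126 127 128 129 130 131 132 133 139 140 141 142 143 144 145 146 147 148 149 150 151 152 153 154 156 157 158 159 160
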