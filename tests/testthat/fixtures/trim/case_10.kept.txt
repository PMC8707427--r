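8 9 10 11 12 13 21 22 23 24 25 26 27 28 29 30 31 32 33 34 35 36 37 38 39 40 41 42 43 44 45 46 47 48 49 50 51 52 53 54 55 56 57 64 65 66 67 68 69 70 71 72 74 75 76 77 78 79 80 81 82 83 84 85 86 87 88 89 90 91 92 93 94 95 103 104 105 106 107 108 109 110 111 112 113 114 115 116 117 118 122 123 124 125 126 127 128 129 130 131 132 133 134 135 136 137 138 139
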