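11 12 13 14 15 16 17 18 37 38 39 40 41 42 43 44 51 52 53 54 55 56 57 58 59 62 63 64 65 66 67 68 69 70 71 76 77 78 79 80 81 82 83 84 85 86 87 88 89 91 92 93 94 95 96 97 98 99 100 101 102 103 104 105 106 107 108 109 110 111 112 113 114 115 116 117 118 119 120 121 124 125 126 127 128 129
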