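"red","green","blue"
255,0,0
255,3,0
255,6,0
255,9,0
255,12,0
255,15,0
255,18,0
255,21,0
255,24,0
255,27,0
255,30,0
255,33,0
255,36,0
255,39,0
255,42,0
255,45,0
255,48,0
255,51,0
255,54,0
255,57,0
255,60,0
255,63,0
255,66,0
255,69,0
255,72,0
255,75,0
255,78,0
255,81,0
255,84,0
255,87,0
255,90,0
255,93,0
255,96,0
255,98,0
255,102,0
255,105,0
255,108,0
255,110,0
255,114,0
255,117,0
255,120,0
255,122,0
255,126,0
255,129,0
255,132,0
255,135,0
255,138,0
255,141,0
255,144,0
255,147,0
255,150,0
255,153,0
255,156,0
255,159,0
255,162,0
255,165,0
255,168,0
255,171,0
255,174,0
255,177,0
255,180,0
255,183,0
255,186,0
255,189,0
255,192,0
255,195,0
255,197,0
255,201,0
255,204,0
255,207,0
255,210,0
255,213,0
255,216,0
255,219,0
255,221,0
255,225,0
255,228,0
255,231,0
255,234,0
255,237,0
255,240,0
255,243,0
255,245,0
255,249,0
255,252,0
255,255,0
251,251,3
248,248,6
245,245,9
243,243,12
240,240,14
236,236,18
234,234,21
231,231,24
227,227,27
225,225,30
222,222,33
219,219,36
216,216,38
212,212,42
210,210,45
207,207,48
203,203,51
200,200,54
197,197,57
195,195,60
192,192,62
188,188,66
186,186,69
183,183,72
179,179,75
177,177,78
174,174,81
171,171,84
168,168,86
164,164,90
162,162,93
159,159,96
155,155,99
152,152,102
149,149,105
147,147,108
144,144,110
140,140,114
138,138,117
135,135,120
131,131,123
129,129,126
125,125,129
122,122,132
120,120,135
117,117,138
114,114,140
110,110,144
107,107,147
104,104,150
101,101,153
98,98,156
96,96,159
93,93,162
89,89,165
86,86,168
83,83,171
80,80,174
77,77,177
74,74,180
72,72,183
69,69,186
66,66,188
62,62,192
59,59,195
56,56,198
53,53,201
50,50,204
48,48,207
45,45,210
41,41,213
38,38,216
35,35,219
32,32,222
29,29,225
26,26,228
24,24,231
21,21,234
18,18,236
14,14,240
11,11,243
8,8,246
5,5,249
2,2,252
0,0,255
0,0,252
0,0,248
0,0,245
0,0,242
0,0,239
0,0,236
0,0,234
0,0,231
0,0,228
0,0,225
0,0,221
0,0,218
0,0,215
0,0,212
0,0,210
0,0,207
0,0,204
0,0,200
0,0,197
0,0,194
0,0,191
0,0,189
0,0,186
0,0,183
0,0,180
0,0,177
0,0,173
0,0,170
0,0,167
0,0,164
0,0,162
0,0,159
0,0,156
0,0,152
0,0,149
0,0,147
0,0,144
0,0,141
0,0,138
0,0,135
0,0,132
0,0,129
0,0,125
0,0,122
0,0,120
0,0,117
0,0,114
0,0,111
0,0,108
0,0,104
0,0,101
0,0,98
0,0,96
0,0,93
0,0,90
0,0,87
0,0,84
0,0,81
0,0,77
0,0,74
0,0,72
0,0,69
0,0,66
0,0,63
0,0,60
0,0,56
0,0,53
0,0,50
0,0,48
0,0,45
0,0,42
0,0,39
0,0,36
0,0,33
0,0,29
0,0,26
0,0,24
0,0,21
0,0,18
0,0,15
0,0,12
0,0,8
0,0,5
0,0,2
0,0,0
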