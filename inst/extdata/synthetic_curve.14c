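# Synthetic stepped calibration curve (test fixture; NOT a measured curve).
# Dialect: header lines prefixed with #; columns cal BP, 14C age BP, sigma.
# Comma-separated; readers must also accept whitespace separation.
28000,26511.8,127
28500,26932.3,129
29000,27407.3,131
29500,27936.8,133
30000,28500.0,135
30500,29063.2,137
31000,29592.7,139
31500,30067.7,141
32000,30488.2,143
32500,30875.0,145
33000,31261.8,147
33500,31682.3,149
34000,32157.3,151
34500,32686.8,153
35000,33250.0,155
35500,33813.2,157
36000,34342.7,159
36500,34817.7,161
37000,35238.2,163
37500,35625.0,165
38000,36011.8,167
38500,36432.3,169
39000,36907.3,171
39500,37436.8,173
40000,38000.0,175
40500,38563.2,177
41000,39092.7,179
41500,39567.7,181
42000,39988.2,183
42500,40375.0,185
43000,40761.8,187
43500,41182.3,189
44000,41657.3,191
44500,42186.8,193
45000,42750.0,195
45500,43313.2,197
46000,43842.7,199
46500,44317.7,201
47000,44738.2,203
47500,45125.0,205
48000,45511.8,207
48500,45932.3,209
49000,46407.3,211
49500,46936.8,213
50000,47500.0,215
50500,48063.2,217
51000,48592.7,219
51500,49067.7,221
52000,49488.2,223
52500,49875.0,225
53000,50261.8,227
53500,50682.3,229
54000,51157.3,231
54500,51686.8,233
55000,52250.0,235
55500,52813.2,237
56000,53342.7,239
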