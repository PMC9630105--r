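# Greenland stadial (GS) / interstadial (GI) phase table, 54-28 kyr BP.
# Onset ages follow the published Greenland ice-core event stratigraphy
# (reported in kyr b2k; converted here to kyr BP by subtracting 0.05).
# This file is user-editable configuration, not a package constant: swap in
# your preferred chronology as long as kinds alternate and phases abut.
name,kind,start_kyr_bp,end_kyr_bp
GI-14,interstadial,54.17,49.55
GS-14,stadial,49.55,49.23
GI-13,interstadial,49.23,48.29
GS-13,stadial,48.29,46.81
GI-12,interstadial,46.81,44.23
GS-12,stadial,44.23,43.29
GI-11,interstadial,43.29,42.19
GS-11,stadial,42.19,41.41
GI-10,interstadial,41.41,40.75
GS-10,stadial,40.75,40.11
GI-9,interstadial,40.11,39.85
GS-9,stadial,39.85,38.17
GI-8,interstadial,38.17,36.53
GS-8,stadial,36.53,35.43
GI-7,interstadial,35.43,34.69
GS-7,stadial,34.69,33.69
GI-6,interstadial,33.69,33.31
GS-6,stadial,33.31,32.45
GI-5.2,interstadial,32.45,31.99
GS-5.2,stadial,31.99,30.79
GI-5.1,interstadial,30.79,30.55
GS-5.1,stadial,30.55,28.85
GI-4,interstadial,28.85,28.55
GS-4,stadial,28.55,27.73
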