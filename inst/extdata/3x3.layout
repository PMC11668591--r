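# 3x3 room maze (reconstruction; synthetic layout, checksum: coverage 11 from start)
name: 3x3
width: 3
height: 3
colors:
purple cyan lime
orange blue magenta
red green yellow
ew_doors:
d d
d d
d d
ns_doors:
d w w
w d d
starts:
0 1
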