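# 3x3 aliased variant (reconstruction; same gates as 3x3, repeated colors)
name: 3x3_alias
width: 3
height: 3
colors:
purple cyan red
orange blue green
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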