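# 4x4 room maze (reconstruction; a Hamiltonian path from the start exists: coverage 15)
name: 4x4
width: 4
height: 4
colors:
white pink teal brown
olive lime navy coral
magenta purple cyan orange
red green blue yellow
ew_doors:
d d d
d d d
d d d
d d d
ns_doors:
w w w d
d d w w
w w d d
starts:
0 0
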