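# Donut maze with the short-path room (2,0) sealed off on all sides
name: Donuts_blocked
width: 5
height: 4
colors:
teal lime purple orange white
brown . . . magenta
olive . . . cyan
red green blue yellow pink
ew_doors:
d d d d
w w w w
w w w w
d w w d
ns_doors:
d w w w d
d w w w d
d w w w d
starts:
0 0
4 0
4 3
0 3
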