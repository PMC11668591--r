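# T maze (reconstruction): 3-room stem, junction, 2-room arms; spawn at the leaves
name: T_maze
width: 5
height: 4
colors:
red green purple cyan white
. . yellow . .
. . blue . .
. . gray . .
ew_doors:
d d d d
w w w w
w w w w
w w w w
ns_doors:
w w d w w
w w d w w
w w d w w
starts:
2 0
0 3
4 3
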