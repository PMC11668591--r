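# Aliased T maze (reconstruction): bottom-stem color visible in three rooms,
# goal color at both arm ends; spawn at the leaves and the junction
name: T_maze_alias
width: 5
height: 4
colors:
red gray purple blue red
. . yellow . .
. . gray . .
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
2 3
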