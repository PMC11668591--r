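# Tolman maze with block B: the segment (3,4)-(3,5) shared by Routes 1 and 2 is walled
name: Tolman_B
width: 7
height: 7
colors:
pink gray blue red . . .
lime . . yellow . . .
brown . . blue olive magenta .
cyan . . green . cyan .
brown . . green . cyan .
teal lime orange gray orange purple .
. . . white . . .
ew_doors:
d d d w w w
w w w w w w
w w w d d w
w w w w w w
w w w w w w
d d d d d w
w w w w w w
ns_doors:
d w w d w w w
d w w w w w w
d w w d w d w
d w w d w d w
d w w d w d w
w w w d w w w
starts:
3 0
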