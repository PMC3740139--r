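at PINK1
color 1 0 1
scale 30
polygon-filled 3
at MPSK1
color 0.92 0.08 0.08
scale 20
circle-lined
at BIKE
color 0 0.67 0
scale 10
text BIKE
legend
scale 20
color 1 0 1
polygon-filled 3
space
text PINK1 is annotated with a pink triangle
next-line
color 0.92 0.08 0.08
circle-lined
space
text MPSK1 is annotated with a red circle
next-line
color 0 0.67 0
text BIKE is annotated in green
legendBox
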