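# Synthetic stand-in for the PROSITE hemolysin-type calcium-binding repeat
# signature (accession PS00330). Constructed from the tandem nonapeptide
# architecture of RTX Ca2+-binding repeats: two consecutive GGXGXDXXX turns.
# Replace this line with the current PROSITE release pattern to use the
# genuine signature; the screen parses whatever pattern stands here.
G-G-x-G-x-D-x-x-x-G-G-x-G-x-D
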