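# Reference stem-loops of the sl56 demonstration fixture.
# S1: minimum-free-energy structure; S2: competing alternative stem-loop.
# Both pre-computed with an external Turner-99 MFE folder (single-base
# dangles); bundled for qualitative demonstration only.
..((...((((((..(((((.((((...)))).)))))..))).)))..)).....
.......................((((((((((((.....)))))..)))))))..
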