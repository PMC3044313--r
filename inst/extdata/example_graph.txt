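# 4-vertex example graph: triangle {1,2,3} plus the pendant edge (1,4)
p 4
1 2
1 3
1 4
2 3
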