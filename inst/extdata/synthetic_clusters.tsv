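cell_id	cluster
cell01	c1
cell02	c1
cell03	c1
cell04	c1
cell05	c1
cell06	c1
cell07	c2
cell08	c2
cell09	c2
cell10	c2
cell11	c2
cell12	c2
cell13	c3
cell14	c3
cell15	c3
cell16	c3
cell17	c3
cell18	c3
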