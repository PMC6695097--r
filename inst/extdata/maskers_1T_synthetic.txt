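the pirate sailed the ocean
she sang a happy song
they cooked the dessert
he rode down the mountain
the doctor played the piano
the nurse climbed the mountain
they can go very fast
he danced by the river
the boats swam in the ocean
she found it loud and purple
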