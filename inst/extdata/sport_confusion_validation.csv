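class,Throw,Serve,Neither
Throw,93,6,0
Serve,4,86,3
Neither,18,8,4
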