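class,Throw,Serve,Neither
Throw,131,3,0
Serve,2,134,3
Neither,5,4,3
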