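{"system":{"nuclei":[{"spin":1,"radical":1,"label":"N5"}]},"hyperfine":[[[-2.6,0,0],[0,-2.6,0],[0,0,49.2]]],"displacement":[4.56,0,0],"eed_tensor":null,"exchange_J":0,"field":{"magnitude":50,"direction":[0,0,1]},"rates":{"kS":3.74,"kT":0.001},"initial":"triplet","noise":null}
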