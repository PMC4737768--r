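{"states":["0","1","2","3","T"],"actions":{"0":["L","R"],"1":["L","R"],"2":["L","R"],"3":["L","R"],"T":"stay"},"transitions":{"0":{"L":{"1":1},"R":{"2":0.5,"3":0.5}},"1":{"L":{"T":1},"R":{"T":1}},"2":{"L":{"T":1},"R":{"T":1}},"3":{"L":{"T":1},"R":{"T":1}},"T":{"stay":{"T":1}}},"rewards":{"0":{"L":0,"R":0},"1":{"L":0.75,"R":0.75},"2":{"L":1,"R":0},"3":{"L":0,"R":1},"T":{"stay":0}},"discount":1,"terminal":"T","start":{"0":1}}
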