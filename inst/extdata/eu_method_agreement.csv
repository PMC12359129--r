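method,cocoso,topsis,edas,waspas,vikor
cocoso,1,0.963777,0.9866,0.9843305,0.96622
topsis,0.963777,1,0.9827,0.986569,0.99451
edas,0.986569,0.982702,1,0.9953195,0.98107
waspas,0.98433,0.986569,0.9953,1,0.98331
vikor,0.966219,0.994505,0.9811,0.983313,1
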