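country,Prevention,Detection and reporting,Rapid response
Alba,70.2,45.0,61.3
Brolland,55.1,62.8,58.9
Corvia,80.6,38.4,49.5
Dorne,43.9,51.2,72.0
Elbonia,66.0,58.7,55.4
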