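region,Prevention,Detection and reporting,Rapid response,Health system,Compliance with norms,Risk environment
European Union,-0.005,-0.013,-0.003,0.018,0.000,0.003
African Region,0.023,-0.032,0.011,-0.004,-0.006,0.008
Eastern Mediterranean,0.051,0.004,-0.003,-0.060,0.004,0.004
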