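region,period,Prevention,Detection and reporting,Rapid response,Health system,Compliance with norms,Risk environment
European Union,2019,0.168,0.372,0.210,0.164,0.044,0.043
European Union,2021,0.162,0.360,0.207,0.182,0.044,0.045
European Union,2017-2021,0.168,0.371,0.200,0.176,0.040,0.044
African Region,2019,0.330,0.326,0.060,0.172,0.057,0.055
African Region,2021,0.352,0.294,0.072,0.169,0.051,0.063
African Region,2017-2021,0.325,0.322,0.061,0.175,0.056,0.061
Eastern Mediterranean,2019,0.209,0.217,0.098,0.322,0.060,0.095
Eastern Mediterranean,2021,0.259,0.221,0.096,0.261,0.063,0.099
Eastern Mediterranean,2017-2021,0.228,0.220,0.092,0.298,0.063,0.099
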