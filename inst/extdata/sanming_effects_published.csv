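year,actual,synthetic,effect
2012,0.4506,0.4731,-0.0225
2013,0.3722,0.4367,-0.0645
2014,0.3614,0.4396,-0.0783
2015,0.3387,0.4769,-0.1382
2016,0.3132,0.4688,-0.1556
2017,0.4243,0.6259,-0.2016
2018,0.4347,0.5893,-0.1546
2019,0.4051,0.5456,-0.1406
2020,0.3549,0.5282,-0.1734
2021,0.3179,0.5154,-0.1976
2022,0.2867,0.5125,-0.2258
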