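predictor,v_weight,treated,synthetic,bias_pct
sec_industry_share,0.0005,47.288,46.9304,-0.76
ter_industry_share,0.0003,33.87,33.5704,-0.88
gdp,0.0004,8400000,8140000,-3.15
household_population,0.001,271.368,265.7329,-2.08
gdp_growth,0,14.04,13.9476,-0.66
misallocation_2010,0.3756,0.5572,0.5479,-1.67
misallocation_2009,0.2453,0.6249,0.6167,-1.32
misallocation_2008,0.1921,0.6789,0.6724,-0.95
misallocation_2007,0.1847,0.7782,0.7723,-0.76
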