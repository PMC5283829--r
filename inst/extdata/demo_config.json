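{"seed":13,"umPerPx":5,"occupancyMethod":"k_sigma","kSigma":5,"minCoverage":0.001,"channelMap":["gfp","mcherry"],"rRangeUm":[40,240]}
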