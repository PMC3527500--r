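species,model,lnL
T. inunguis,M2,-12874
T. inunguis,M3,-14620
T. inunguis,M1,-36179
T. inunguis,M0,-168836
T. manatus,M3,-50962
T. manatus,M1,-82139
T. manatus,M2,-140693
T. manatus,M4,-838113
T. manatus,M0,-2254637
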