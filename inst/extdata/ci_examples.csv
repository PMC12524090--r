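split,accuracy_pct,ci_lower,ci_upper,standard_error,n
90/10,98.39,97.71,99.07,0.00348,1311
40/60,96.87,95.93,97.81,0.00481,1311
10/90,90.08,88.46,91.70,0.00825,1311
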