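column,n,tfc,tms,sdmt,swr,cuhdrs
total,2626,12.88,2.56,54.47,100.78,17.16
slow,1524,12.92,1.79,55.41,100.79,17.32
fast,1102,12.82,3.58,53.23,100.77,16.95
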