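analysis,scheme,group,kind,printed_r2
sector linear,sectors,control,linear,0.17
sector linear,sectors,case,linear,0.96
etdrs 5-10 linear,etdrs,control,linear,0.58
etdrs 5-10 linear,etdrs,case,linear,0.28
etdrs 10-20 linear,etdrs,control,linear,0.59
etdrs 10-20 linear,etdrs,case,linear,0.91
ring exponential,rings,control,exponential,0.97
ring exponential,rings,case,exponential,0.95
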