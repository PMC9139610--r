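group,n,mean,sd
control,12,31.1,6.2
case,10,21.8,5.9
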