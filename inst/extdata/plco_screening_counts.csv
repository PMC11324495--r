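strategy,tp,fp,fn,tn
traditional,1040,1139,2536,24530
improved1,2832,7651,744,18018
improved2,2719,6974,857,18695
improved3,1498,2484,2078,23185
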