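name,formula,molecular_weight,n_nco_groups,metabolite
MDI,C15H10N2O2,250.25,2,MDA
TDI,C9H6N2O2,174.16,2,TDA
HDI,C8H12N2O2,168.20,2,HDA
IPDI,C12H18N2O2,222.28,2,IPDA
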