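method,dpc,dg,voe,ravd,assd
full,0.6951,0.8182,0.4395,0.3861,10.80
no_fsmf,0.6707,0.8136,0.4427,0.7484,16.39
no_confft,0.6591,0.6115,0.4822,0.4838,12.64
no_gmca,0.6132,0.7725,0.5225,0.5838,22.17
no_maha,0.6783,0.8089,0.4467,0.4155,11.69
one_branch,0.6669,0.6794,0.4739,0.4929,25.09
concat,0.6839,0.7257,0.4593,0.4559,15.59
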