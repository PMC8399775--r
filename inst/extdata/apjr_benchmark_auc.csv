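table,score,auc
single_model,minE,0.142
single_model,avgE,0.164
single_model,BStot,0.464
single_model,BS1,0.664
single_model,BScritical,0.656
ensemble,Model_ini,0.664
ensemble,MD,0.665
ensemble,HMC,0.725
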