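name,acid_base,pka,logp_values,free_base_solubility,cmc,molecular_volume,surface_active,aggregation_number,zp_mV,ph_measured
AMI,weak_base,9.4,5.84;4.97;4.54;4.86;4.7,3.5e-5,3.6e-2,4.2e-28,TRUE,7,45.3,6.676
COU,weak_acid,2.98,4.89;4.92;3.47;5.48,3e-10,NA,5.8e-28,FALSE,NA,-22.8,7.203
CUR,weak_base,8.11,3.20;3.15;1.47;4.04;2.5,7e-8,NA,6.1e-28,FALSE,NA,1.0,6.784
NOR,weak_base,10.0,5.31;4.63;4.31;4.92;3.57,2.6e-5,5e-2,4.1e-28,TRUE,NA,15.6,9.605
PRO,weak_base,7.66,2.86;2.21;3.85;3,4.5e-6,1.2e-2,6.5e-28,TRUE,NA,-44.1,12.426
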