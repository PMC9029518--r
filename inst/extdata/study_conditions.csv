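variant,compound,c0_saturation_mM,solvent,antisolvent_naoh_mM,antisolvent_nominal_ph,centrifuge_min
AMIa,AMI,79.7,ethanol,0.25,10.4,20
AMIb,AMI,79.7,ethanol,1.0,11,20
COU,COU,6.28,ethanol,0,7,20
CUR,CUR,6.79,ethanol,0,7,20
NOR,NOR,50.0,ethanol,1.0,11,30
PRO,PRO,9.07,acetone_naoh,1.0,11,20
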