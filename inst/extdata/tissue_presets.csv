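species,tissue,measure,mean,sd
rat,ACL,csa,0.26,0.04
rat,PCL,csa,0.35,0.08
rat,MCL,csa,0.17,0.03
rat,LCL,csa,0.24,0.09
mouse,ACL,csa,0.029,0.007
mouse,PCL,csa,0.041,0.015
mouse,MCL,csa,0.031,0.007
mouse,LCL,csa,0.054,0.017
rat,ACL,norm_csa,0.78,0.11
rat,PCL,norm_csa,1.10,0.20
rat,MCL,norm_csa,0.50,0.10
rat,LCL,norm_csa,0.71,0.30
mouse,ACL,norm_csa,0.52,0.15
mouse,PCL,norm_csa,0.71,0.30
mouse,MCL,norm_csa,0.54,0.14
mouse,LCL,norm_csa,0.95,0.30
rat,MEN,width_anterior,1.18,0.30
rat,MEN,width_central,0.70,0.16
rat,MEN,width_posterior,1.13,0.30
rat,MEN,height,0.82,0.16
mouse,MEN,width_anterior,0.49,0.17
mouse,MEN,width_central,0.35,0.07
mouse,MEN,width_posterior,0.41,0.11
mouse,MEN,height,0.30,0.07
rat,PLATEAU,area,33.35,2.80
mouse,PLATEAU,area,5.67,0.50
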