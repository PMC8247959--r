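pH,k_obs_per_s,se_per_s
3,2.530062e-06,2.530062e-07
3.5,8.89142699655341e-07,8.89142699655341e-08
4,3.7062e-07,3.7062e-08
4.5,2.07855275993345e-07,2.07855275993345e-08
5,1.602e-07,1.602e-08
5.5,1.57195587877448e-07,1.57195587877448e-08
6,1.944e-07,1.944e-08
6.5,3.2682016156888e-07,3.2682016156888e-08
7,7.5024e-07,7.5024e-08
7.5,2.09068804396824e-06,2.09068804396824e-07
8,6.330024e-06,6.330024e-07
8.5,1.97361290825103e-05,1.97361290825103e-06
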