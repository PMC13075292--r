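# Literature limiting mobilities and diffusion coefficients at 25 C for the
# ions of the crystal-violet / hydroxide titration system. CV+ values are
# synthetic literature-order estimates for a bulky triarylmethane cation and
# should be overridden when measured values are available.
name,charge_sign,mobility_m2_V_s,diffusion_m2_s,init_conc_left,init_conc_right
K+,1,7.62e-08,1.957e-09,0.001,0.001
Na+,1,5.19e-08,1.334e-09,0.002,0.002
Cl-,-1,7.91e-08,2.032e-09,0.001,0.001
Acetate-,-1,4.24e-08,1.089e-09,0.002,0.002
OH-,-1,2.05e-07,5.273e-09,0,0.2
CV+,1,2.5e-08,6.4e-10,0.2,0
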