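label,method,n,ka,dh,dg,tds,temperature
CT@CB7,itc,0.99,1.44e4,-13.23,-5.69,-7.57,298.15
CT@CB7,nmr,NA,6.57e3,NA,-5.21,NA,298.15
FT@CB7,itc,1.12,4.95e4,-11.08,-6.40,-4.68,298.15
FT@CB7,uvvis,NA,1.30e4,NA,-5.62,NA,298.15
NT@CB7,itc,0.95,1.34e4,-15.60,-5.64,-9.96,298.15
NT@CB7,uvvis,NA,1.05e5,NA,-6.85,NA,298.15
CT@CB7,mmgbsa,NA,NA,-37.55,-17.45,-20.10,298.15
FT@CB7,mmgbsa,NA,NA,-33.12,-12.25,-20.86,298.15
NT@CB7,mmgbsa,NA,NA,-32.47,-12.79,-19.68,298.15
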