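substance,center,amplitude,fwhm
teflon,292,1,12
teflon,385,1,12
teflon,734,1,12
teflon,1218,1,12
teflon,1302,1,12
teflon,1382,1,12
pork,1064,1,12
pork,1300,1,12
pork,1441,1,12
pork,1656,1,12
PS,1035,1,12
PMMA,600,1,12
paracetamol,800,1,12
paracetamol,860,1,12
aspirin,752,1,12
aspirin,1047,1,12
caffeine,1703,1,12
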