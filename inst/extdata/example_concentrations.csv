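id,water_type,river,Fe,Mn,Cu,Zn,Al,Hg,As,Se,Cd,Pb,Li,B,Ba,Sb,Ni,Co,Mo
W01,surface,Main,412.5,35.2,1.4,48.9,310.2,<MDL,0.62,0.35,0.41,0.28,2.1,21.4,48.0,<MDL,2.2,0.45,0.61
W02,surface,Main,388.0,28.7,1.1,52.3,295.8,0.08,0.55,<MDL,0.38,0.22,1.9,19.8,45.1,0.18,1.9,0.41,0.55
W03,surface,Xichong,521.3,44.1,1.8,61.0,402.7,0.12,0.91,0.44,0.62,0.31,2.6,24.9,52.3,0.21,2.8,0.58,0.72
W04,ground,Xichong,96.4,12.3,0.8,30.1,88.5,<MDL,0.38,0.29,0.21,0.15,1.2,14.2,38.7,<MDL,1.4,0.22,0.34
W05,mine,Yangchang,748.9,88.6,2.4,95.2,610.3,0.19,1.42,0.61,0.98,0.44,3.8,31.5,66.8,0.29,4.1,0.92,1.05
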