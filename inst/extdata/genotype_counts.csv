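rsid,gene,cluster,marker_model,n_AA,n_AB,n_BB,n_positive,n_null
rs861539,XRCC3,repair,codominant,95,38,18,NA,NA
rs1799782,XRCC1,repair,codominant,102,41,8,NA,NA
rs25487,XRCC1,repair,codominant,50,63,38,NA,NA
rs13181,XPD,repair,codominant,88,55,8,NA,NA
rs17861084,CYP1A1,detox,codominant,134,0,17,NA,NA
rs8192718,CYP2B6,detox,codominant,132,2,17,NA,NA
rs186133763,CYP2D6,detox,codominant,134,0,17,NA,NA
rs11592737,CYP2C19,detox,codominant,115,29,7,NA,NA
GSTT1_del,GSTT1,detox,dominant_deletion,NA,NA,NA,128,89
GSTM1_del,GSTM1,detox,dominant_deletion,NA,NA,NA,110,110
rs1138272,GSTP1,detox,codominant,115,17,19,NA,NA
rs1695,GSTP1,detox,codominant,87,50,14,NA,NA
rs1871042,GSTP1,detox,codominant,72,48,31,NA,NA
rs138002121,SOD1,antioxidant,codominant,133,1,17,NA,NA
rs1041740,SOD1,antioxidant,codominant,59,55,37,NA,NA
rs2237329,NFE2L3,antioxidant,codominant,106,23,22,NA,NA
rs713041,GPX4,antioxidant,codominant,21,97,33,NA,NA
rs41303970,GCLM,antioxidant,codominant,117,27,7,NA,NA
rs12524550,GCLC,antioxidant,codominant,131,3,17,NA,NA
rs3799694,GCLC,antioxidant,codominant,81,55,15,NA,NA
rs524553,GCLC,antioxidant,codominant,126,23,2,NA,NA
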