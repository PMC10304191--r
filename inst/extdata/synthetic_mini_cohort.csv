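"id","village","sex","age","weight","smoking","alcohol","cons_meat","cons_cucumbers","cons_tomatoes","cons_peppers","cons_apples","cons_pears","cons_milk","rs861539","rs1799782","rs25487","rs13181","rs17861084","rs8192718","rs186133763","rs11592737","GSTT1_del","GSTM1_del","rs1138272","rs1695","rs1871042","rs138002121","rs1041740","rs2237329","rs713041","rs41303970","rs12524550","rs3799694","rs524553","questionnaire"
"MINI-01","Kyzylkairat","F",40,60,0,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,0,1,0,0,0,1,0,"+","+",1,0,0,0,1,0,0,0,1,0,0,TRUE
"MINI-02","Kyzylkairat","M",45,70,1,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,1,0,0,0,1,0,0,"+","-",0,0,0,1,0,0,0,1,0,0,0,TRUE
"MINI-03","Kyzylkairat","F",50,80,0,1,0.1,0.1,0.2,0.05,0.2,0.1,0.5,1,0,0,0,1,0,0,0,"-","+",0,0,1,0,0,0,1,0,0,0,1,TRUE
"MINI-04","Kyzylkairat","M",55,65,1,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,0,0,1,0,0,0,1,"+","+",0,1,0,0,0,1,0,0,0,1,0,TRUE
"MINI-05","Kyzylkairat","F",60,75,0,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,0,1,0,0,0,1,0,"+","+",1,0,0,0,1,0,0,0,1,0,0,TRUE
"MINI-06","Kyzylkairat","M",35,70,1,1,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,1,0,0,0,1,0,0,"+","-",0,0,0,1,0,0,0,1,0,0,0,TRUE
"MINI-07","Karakastek","F",42,60,0,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,1,0,0,0,1,0,0,0,"-","+",0,0,1,0,0,0,1,0,0,0,1,TRUE
"MINI-08","Karakastek","M",48,80,1,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,0,0,1,0,0,0,1,"+","+",0,1,0,0,0,1,0,0,0,1,0,TRUE
"MINI-09","Karakastek","F",52,70,0,1,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,0,1,0,0,0,1,0,"+","+",1,0,0,0,1,0,0,0,1,0,0,TRUE
"MINI-10","Karakastek","M",38,65,1,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,1,0,0,0,1,0,0,"+","-",0,0,0,1,0,0,0,1,0,0,0,TRUE
"MINI-11","Karakastek","F",64,75,0,0,0.1,0.1,0.2,0.05,0.2,0.1,0.5,1,0,0,0,1,0,0,0,"-","+",0,0,1,0,0,0,1,0,0,0,1,TRUE
"MINI-12","Karakastek","M",46,85,1,1,0.1,0.1,0.2,0.05,0.2,0.1,0.5,0,0,0,1,0,0,0,1,"+","+",0,1,0,0,0,1,0,0,0,1,0,TRUE
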