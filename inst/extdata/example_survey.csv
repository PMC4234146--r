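hhid,community,zlen,age_months,sex,mom_school,income,cur,crowding,water,toilet,died,elec,floor,fuel,has_radio,has_tv,has_fridge,has_mobile
B001,riverside,-2.6,30,0,3,4500,XTS,3.5,no,no,0,0,1,1,no,no,no,yes
B002,riverside,-1.2,45,1,8,9000,XTS,2.0,yes,no,0,1,1,1,yes,yes,no,yes
B003,riverside,0.3,55,0,12,21000,XTS,1.2,yes,yes,0,1,0,0,yes,yes,yes,yes
B004,hillside,-2.1,28,1,0,3000,XTS,4.0,no,no,1,0,1,1,no,no,no,no
B005,hillside,-0.8,38,0,6,8000,XTS,1.8,yes,yes,0,1,0,1,yes,no,no,yes
B006,hillside,-1.5,50,1,10,15000,XTS,1.5,yes,yes,0,1,0,0,yes,yes,yes,yes
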