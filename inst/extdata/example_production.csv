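country_id,crop_id,year,quantity
USA,apple,2000,4681890
USA,soybean,2000,75055300
USA,almond,2000,538590
CHN,apple,2000,20437100
CHN,soybean,2000,15409300
CHN,wheat,2000,99636000
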