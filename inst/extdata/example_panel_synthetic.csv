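"site","year","snails","temp"
"S01",1,24.1147851199632,15.9416542861214
"S01",2,25.1458497071515,18.9111021929372
"S01",3,23.7962539107642,17.0856881510395
"S01",4,26.7835913005106,18.5479329548588
"S01",5,23.498982305395,16.5335587857287
"S01",6,24.8227584659657,16.1867759033367
"S02",1,25.0889312373413,16.9204129761539
"S02",2,26.1229343065936,17.2363950685884
"S02",3,22.3307782886064,14.0256841482676
"S02",4,27.2319807857001,18.637879587537
"S02",5,23.0792829188491,15.2963251037322
"S02",6,25.1089253797972,15.3633868727176
"S03",1,25.5126346679022,13.8911299640601
"S03",2,26.4918888314889,13.4795385094037
"S03",3,25.0789980989693,13.5585988066395
"S03",4,23.3250263594175,12.8451791578945
"S03",5,25.6665704166688,11.7956613117223
"S03",6,26.741024612671,14.2621868390263
"S04",1,23.8025186565268,14.8775802265234
"S04",2,23.4433310529097,16.6470573032961
"S04",3,21.9259353346015,14.5290125229833
"S04",4,28.34619774744,17.8390328883823
"S04",5,25.3693572049043,16.114196533154
"S04",6,25.0656136127842,16.5368903456934
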