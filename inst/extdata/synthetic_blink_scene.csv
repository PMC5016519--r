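x_nm,y_nm,frame
1149.920306483773,127.51493356731727,294
1138.991579500151,120.32376898923614,825
374.2568610934718,1102.8498608340428,1260
1141.9416661007117,128.00382238493523,3099
1102.8464276636098,17.54793682988288,3374
327.6298565814803,306.8195049614655,3642
286.9319246687849,19.363409947458408,3929
282.46283518442505,13.20040583749936,4074
422.1151639008233,1458.5589104935827,4337
1142.9989975751748,111.22062398752416,5343
364.3242000360899,1102.9383286977957,6298
1134.4387303548997,129.87692525474444,6450
418.92877540542355,1972.060396704879,6493
281.1044778858845,23.465451734055492,6564
1384.6677633714758,979.994885104179,7151
365.87533459479204,1096.076217257126,7770
418.3216226612832,1459.057606520837,7919
425.6754088408105,1448.8581703048776,8227
1130.0325714994544,127.64600839645955,8362
473.7387290149891,78.66230801807234,8658
1098.8728192678427,35.050192800174194,9017
1143.711485109229,138.61831723851623,9318
370.52444706376997,1114.010043887692,9347
320.6229556390886,291.77595248361195,9780
281.26153867821404,10.551287277758096,10186
1089.9259352093427,37.13490099595574,10543
370.72027210012135,1082.9993115148377,10574
796.6828249942059,762.2167278653957,10979
1149.9760402843415,111.05634606370539,11230
287.6393338039137,15.811824825615865,11648
1097.8793100108567,30.966469802040752,12141
1153.718994680568,117.03641108563674,12263
1143.150140063015,113.8349005723356,12453
479.25076327992264,91.66436389475405,13584
434.6452650455496,1447.7931638629102,14037
431.61120393303156,1458.0628064113082,14089
438.0196010252415,1456.5055843134553,14401
1157.6609257117664,142.22154059850953,14463
270.9411887190907,10.215328255742556,14919
362.77194746489096,1120.3740403837423,15111
361.88248511600597,1102.999756582704,15607
421.3949074512247,1477.4849121093355,16000
1098.8571299323312,26.706721300764727,16370
329.1624244501784,305.64132296366796,17009
804.1147103741367,765.5805230650014,17561
325.7407485811865,299.27936228632194,17883
312.049100240305,297.8038916843136,18485
794.1912077793166,758.8825171055407,18561
799.3848713509894,755.9074465446043,19706
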