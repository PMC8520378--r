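# kind: piecewise_smooth
# components: 4
# seed: 1
# N: 300
# generator: cspa::generate_test_signal
0.62357254093512893
0.6189389108496357
0.61422631512755288
0.60943475376888046
0.60456422677361843
0.5996147341417668
0.59458627587332558
0.58947885196829475
0.58429246242667432
0.57902710724846429
0.57368278643366466
0.56825949998227543
0.5627572478942966
0.55717603016972816
0.55151584680857013
0.5457766978108225
0.53995858317648526
0.53406150290555843
0.52808545699804199
0.52203044545393595
0.51589646827324032
0.50968352545595508
0.50339161700208024
0.4970207429116158
0.49057090318456176
0.48404209782091812
0.47743432682068487
0.47074759018386203
0.46398188791044959
0.45713722000044754
0.4502135864538559
0.44321098727067465
0.4361294224509038
0.42896889199454336
0.42172939590159331
0.41441093417205366
0.40701350680592441
0.39953711380320556
0.39198175516389711
0.38434743088799905
0.3766341409755114
0.36884188542643415
0.36097066424076729
0.35302047741851084
0.34499132495966478
0.33688320686422912
0.32869612313220387
0.32043007376358901
0.31208505875838455
0.30366107811659049
0.29515813183820683
0.28657621992323357
0.2779153423716707
0.26917549918351824
0.26035669035877618
0.25145891589744451
0.24248217579952325
0.23342647006501238
0.22429179869391191
0.21507816168622185
0.20578555904194218
0.19641399076107291
0.18696345684361404
0.17743395728956557
0.1678254920989275
0.15813806127169983
0.14837166480788255
0.13852630270747568
0.1286019749704792
0.11859868159689313
0.10851642258671745
0.098355197939952177
0.0881150076565973
0.077795851736652821
0.067397730180118742
0.056920642986995063
0.046364590157281782
0.035729571690978901
0.025015587588086419
0.014222637848604336
0.0033507224725326523
-0.007600158540128632
-0.018630005189379517
-0.029738817475220003
-0.04092659539765009
-0.052193338956669777
-0.063539048152279065
-0.074963722984477954
-0.086467363453266444
-0.098049969558644534
-0.10971154130061223
-0.12145207867916952
-0.13327158169431641
-0.1451700503460529
-0.157147484634379
-0.16920388455929469
-0.18133925012079999
-0.19355358131889489
-0.20584687815357938
-0.21821914062485348
-0.23067036873271718
-0.24320056247717048
-0.25580972185821338
-0.26849784687584588
-0.28126493753006798
-0.29411099382087968
-0.30703601574828099
-0.32004000331227189
-0.3331229565128524
-0.3462848753500225
-0.35952575982378221
-0.37284560993413152
-0.38624442568107042
-0.39972220706459893
-0.41327895408471704
-0.42691466674142475
-0.44062934503472206
-0.45442298896460898
-0.46829559853108549
-0.4822471737341516
-0.49627771457380732
-0.51038722105005263
-0.52457569316288755
-0.53884313091231206
-0.55318953429832618
-0.5676149033209299
-0.58211923798012322
-0.59670253827590614
-0.61136480420827866
1.8740456933155656
1.8681752462650276
1.8630932328740912
1.858799653142756
1.8552945070710221
1.8525777946588897
1.8506495159063585
1.8495096708134287
1.8491582593801001
1.8495952816063728
1.8508207374922467
1.8528346270377223
1.855636950242799
1.8592277071074772
1.8636068976317566
1.8687745218156375
1.8747305796591196
1.881475071162203
1.8890079963248878
1.8973293551471742
1.9064391476290614
1.9163373737705502
1.9270240335716404
1.938499127032332
1.9507626541526248
1.9638146149325189
1.9776550093720142
1.9922838374711109
2.0077010992298092
2.0239067946481084
2.0409009237260092
2.0586834864635115
2.077254482860615
2.09661391291732
2.1167617766336262
2.1376980740095335
2.1594228050450424
2.1819359697401524
1.4953984841704369
1.4997600747005795
1.5043107871433827
1.5090506214988466
1.5139795777669713
1.5190976559477567
1.5244048560412027
1.5299011780473095
1.535586621966077
1.5414611877975051
1.5475248755415938
1.5537776851983436
1.5602196167677538
1.5668506702498248
1.5736708456445563
1.5806801429519488
1.5878785621720017
1.5952661033047155
1.6028427663500902
1.6106085513081252
1.6185634581788213
1.6267074869621776
1.635040637658195
1.643562910266873
1.6522743047882118
1.6611748212222111
1.6702644595688712
1.6795432198281919
1.6890111020001735
1.6986681060848154
1.7085142320821185
1.718549479992082
1.7287738498147063
1.7391873415499912
1.749789955197937
1.7605816907585434
1.7715625482318105
1.7827325276177384
1.7940916289163267
1.8056398521275761
1.8173771972514858
1.8293036642880565
1.8414192532372877
1.8537239640991796
1.8662177968737323
1.8789007515609457
1.8917728281608197
1.9048340266733548
1.91808434709855
1.9315237894364063
1.9451523536869231
1.9589700398501009
1.9729768479259393
1.9871727779144384
2.001557829815598
2.0161320036294184
2.0308952993558997
2.0458477169950413
2.0609892565468435
2.0763199180113068
2.0918397013884311
2.1075486066782152
2.1234466338806608
2.1395337829957666
2.1558100540235334
2.1722754469639609
2.188929961817049
2.2057735985827978
2.2228063572612076
2.240028237852278
2.2574392403560086
2.2750393647723999
2.2928286111014522
2.3108069793431656
2.3289744694975392
2.3473310815645734
2.3658768155442687
2.3846116714366246
2.4035356492416411
2.4226487489593183
2.441950970589656
2.4614423141326549
2.4811227795883144
2.5009923669566341
2.5210510762376148
2.5412989074312566
2.5617358605375586
2.5823619355565213
2.603177132488145
2.6241814513324293
2.6453748920893743
2.6667574547589794
2.6883291393412461
2.7100899458361729
2.7320398742437608
2.7541789245640094
2.7765070967969185
2.7990243909424883
2.8217308070007188
2.8446263449716103
2.8677110048551619
2.8909847866513747
2.9144476903602481
1.2600703588686883
1.2802382938255967
1.3024737923073846
1.3267768543140517
1.3531474798455985
1.3815856689020247
1.4120914214833304
1.4446647375895154
1.4793056172205801
1.5160140603765244
1.554790067057348
1.5956336372630509
1.6385447709936334
1.6835234682490954
1.7305697290294366
1.779683553334658
1.8308649411647582
1.884113892519738
1.9394304073995974
1.996814485804336
2.0562661277339545
2.1177853331884524
2.1813721021678294
2.2470264346720863
2.3147483307012222
2.384537790255238
2.4563948133341329
2.5303193999379072
2.6063115500665615
2.6843712637200952
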