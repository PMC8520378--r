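# group: water
# phase: pre
# enhancement_factor: 3
# seed: 1
# noise_sigma: 0.01
# generator: cspa::simulate_contrast_experiment
-0.0062645381074233246
0.0018364332422208223
-0.0083562861241004722
0.015952808021377916
0.0032950777181536051
-0.0082046838411801524
0.0048742905242848533
0.0073832470512921735
0.005757813516534923
-0.0030538838715635603
0.01511781168450848
0.003898432364114311
-0.0062124058054180377
-0.022146998871775
0.011249309181431083
-0.00044933609015230852
-0.00016190263098946089
0.0094383621068529922
0.0082122119509808848
0.0059390132121750882
0.0091897737160821832
0.0078213630073106707
0.000745649833651906
-0.019893516958633728
0.0061982574789471029
-0.00056128739529000781
-0.001557955067053293
-0.014707523838992745
-0.0047815005510862037
0.004179415601997024
0.013586795515290439
-0.0010278772734299553
0.0038767161155936914
-0.00053805040582905123
-0.013770595568286066
-0.0041499456329967977
-0.0039428995371034933
-0.00059313396711185666
0.011000253719838831
0.0076317574845754426
-0.001645235962535869
-0.0025336168013650757
0.0069696337540473743
0.0055666319867365734
-0.006887556945495199
-0.007074951569621196
0.003645819621368303
0.0076853292451541577
-0.0011234621215022807
0.0088110772645421474
0.0039810588036706803
-0.0061202639325077125
0.003411196914244248
-0.011293630960807925
0.01433023701701037
0.0198039989850586
-0.0036722147646650904
-0.010441346263165308
0.0056971962744241291
-0.0013505460388082435
0.024016177605047765
-0.00039240002733169246
0.0068973936245077675
0.00028002158780666064
-0.0074327320888240532
0.001887922995143429
-0.018049586288910378
0.01465554861562886
0.0015325333821189771
0.021726116703621529
0.0047550952889966252
-0.0070994643092181457
0.0061072635348905493
-0.0093409763164425154
-0.012536334002391021
0.0029144623551746285
-0.0044329187321843298
1.1053516316241312e-05
0.00074341324151664062
-0.0058952094618807196
-0.0056866873281850193
-0.0013517861512383207
0.011780869965732044
-0.01523566800429762
0.0059394618762842154
0.003329503712135183
0.010630998372763626
-0.0030418392363430065
0.0037001880991628816
0.0026709879077223102
-0.0054252003099165037
0.012078678059831722
0.011604026156949516
0.0070021364951499826
0.015868334545408456
0.0055848642556530397
-0.012765922084580366
-0.0057326541423688626
-0.012246126148983558
-0.0047340063643931162
-0.0062036667722412423
0.00042115873144235241
-0.0091092164855244556
0.0015802877240407498
-0.0065458464391881781
0.017672872693726461
0.007167074760172058
0.0091017422949522721
0.0038418535782634463
0.016821760805194184
-0.0063573645394897705
-0.0046164473036056607
0.01432282238541663
-0.0065069635331036673
-0.0020738074360196544
-0.0039280792944198393
-0.0031999286854850683
-0.0027911330297655896
0.0049418833126782706
-0.0017733048226960639
-0.0050595746211425738
0.013430388251704116
-0.0021457940854686872
-0.0017955653004338712
-0.0010019074121356197
0.007126663070514053
-0.00073564404126326335
-0.00037634171467047913
-0.0068166047875565699
-0.0032427027224631905
0.00060160440434515159
-0.0058889448625966383
0.0053149619263257245
-0.015183940817867872
0.0030655786078976561
-0.015364498235375862
-0.0030097612683661068
-0.005282799044450062
-0.0065209478068099878
-0.00056896777847392549
-0.019143594256800119
0.011765833120185625
-0.016649724362120033
-0.0046353040147238565
-0.011159201050428454
-0.0075081900119344791
0.020871665456283467
0.00017395619693251661
-0.012863005304343256
-0.016406055344185783
0.0045018710127265552
-0.00018559832714637982
-0.0031806837454384442
-0.0092936214745370244
-0.014874603101414847
-0.010751922966156808
0.010000288037139142
-0.0062126669479682338
-0.013844268473844915
0.018692906224235806
0.0042510037737244792
-0.0023864710091303278
0.0105848304870902
0.0088642265137493601
-0.0061924304823114708
0.022061024645404676
-0.0025502703014101524
-0.014244946502128084
-0.0014439960195421942
0.0020753833923234477
0.023079783990593614
0.0010580236789371146
0.0045699880542341351
-0.00077152935356530981
-0.003340008423665445
-0.00034726028311276192
0.0078763960563016187
0.02075245008652285
0.010273924387637681
0.012079083983867039
-0.01231323421558044
0.0098389557005337924
0.002199248036606513
-0.014672500290922427
0.005210227426481388
-0.0015875460471601599
0.014645873119697974
-0.0076608199960466481
-0.0043021175392854655
-0.0092610949737743729
-0.0017710396143654026
0.0040201177948633784
-0.0073174817311960636
0.0083037316798167376
-0.01208082786304465
-0.010479844128077415
0.014411577068442809
-0.010158474653046491
0.0041197471231751489
-0.0038107605110891964
0.0040940183965093406
0.016888732862040463
0.015865884334419704
-0.0033090780068276635
-0.02285235535292467
0.024976615898341641
0.0066706616676549301
0.005413273359637003
-0.00013399523145908701
0.005101084229529265
-0.0016437583176966725
0.0042069464325451278
-0.0040024674397764384
-0.013702078775474604
0.0098783826745487864
0.015197450254995455
-0.0030874056922561366
-0.012532897556076911
0.0064224130567782376
-0.00044709136893979125
-0.017332184068248383
2.1318596802696483e-05
-0.0063030033392814612
-0.0034096857986040518
-0.011565723626358533
0.01803141907917467
-0.0033113203639122107
-0.016055134122530776
0.0019719343873948075
0.0026317564640547376
-0.0098582670040929087
-0.02888920671679545
-0.0064048170256511498
0.0057050763592048463
-0.00059723276042610051
-0.0009817874400523442
0.0056082072862011613
-0.011864586385794738
0.010967770442742431
-5.3440282781656926e-05
0.0070731066739807896
0.010341077347374621
0.0022348041491530436
-0.0087870761286601862
0.011629645559673303
-0.020001649447854757
-0.0054479074000172477
-0.002556707091569888
-0.0016612103676500616
0.010204639087841076
0.0013622189310277767
0.0040716760342383645
-0.00069654813012904855
-0.0024766434161933083
0.0069555080661964017
0.01146228357215801
-0.024030962148918717
0.0057273955524584051
0.0037472440677865466
-0.0042526772155607627
0.0095101280757681639
-0.0038923718171837889
-0.0028433066179957352
0.0085740977807980331
0.017196272991206015
0.002700549009372289
-0.0042218400978764007
-0.011891132948595852
-0.0033103297887900978
-0.0093982932651002146
-0.0025893258311878485
0.0039437916822157217
-0.0085185709202386349
0.026491668810948801
0.001560116756650789
0.011302072674549427
-0.022891239798401054
0.007410011571954386
-0.013162451604515617
0.0091980367760914131
0.0039813015545195609
-0.0040752857926977205
0.013242586301772727
-0.0070123166924691959
-0.0058061430424053619
-0.010010721810254187
-0.0066817860675339345
0.0094518495337308234
0.0043370214954516198
0.010051592176770431
-0.0039011866405367869
0.003763702917746482
0.0024416492448649423
-0.014262573423825382
0.017784292874754512
0.0013444766093367595
0.0076559899915786423
0.0095513667690898165
-0.00050565701442270127
-0.0030581541976697105
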