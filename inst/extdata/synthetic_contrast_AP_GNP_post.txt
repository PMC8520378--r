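# group: AP_GNP
# phase: post
# enhancement_factor: 3
# seed: 1
# noise_sigma: 0.01
# generator: cspa::simulate_contrast_experiment
0.0089367370242551328
-0.010472981490612954
0.019713373862241517
-0.0038363210628836217
0.016541453022749893
0.015122126939506295
0.0008296573358591399
0.0056722091485149964
-0.010245484795344604
0.0032300650302243645
0.010436124583561827
0.00099078486897198202
-0.0045413690915436043
-0.0065578185245044008
-0.00035922422622511351
0.010691614606767963
-0.0048397493030127694
-0.0012101011132744377
-0.012941400038208409
0.0049431283601485626
0.013079015201141457
0.014970410094027832
0.0081470273089735631
-0.018697887902026127
0.0048202950412375989
0.0045613560330120193
-0.0035340028582991128
0.0017048947094798195
-0.0086403595412690368
0.0067923077401565585
-0.0032710101465310442
-0.01569082185143952
-0.0036745075617048151
0.013644349290698478
-0.0033428136473116392
0.0073275004220910199
0.0094658564019778606
4.3987043263740258e-05
-0.0035232230554984884
-0.0052969550913350393
0.0073958922557479639
-0.010634574154828123
0.0024621084353639976
-0.0028949936656431181
-0.022648893564879438
-0.014088504560731938
0.0091601932879257358
-0.0019127895053519955
0.0080328321613364756
0.018874744633086048
0.014738811811091381
0.0067726849231299832
0.0037996268656674461
-0.00192798426457334
0.015778917949043996
0.0059623410931845394
-0.011735769408713594
-0.0015564253489031819
-0.019189098202698408
-0.0019525884611063661
-0.025923276699459867
0.013140021671980534
-0.0063554300103213527
-0.0042997883869418801
-0.0016931833230196295
0.0061221817398912819
0.0067834017722269982
0.0056795197247167181
-0.005725426039261257
-0.013632912562783402
-0.0038872224433790072
0.0027791413245054292
-0.0082308112157202448
-0.000688409344784646
-3.0116766232612964
-2.500083090142156
-1.9987114459840278
-1.5014587562846091
-1.0016391095673616
-0.48236447997214899
0.0076258651241831836
0.51111431080730452
0.99076793047169809
1.5016434183842831
2.0115482518709746
2.499434785754735
2.9787063935176517
0.003448457620994559
-0.019049554455855294
-0.0081117015314021712
0.01324004321299602
0.0061563684930267442
0.010916689555353609
0.0030660486151363226
-0.0011015876248285665
-0.0092431277312728394
0.015929137537191954
0.00045010598121880306
-0.007151284006678825
0.0086522309971713788
0.010744409582779002
0.0189565477419858
-0.0060299730360509445
-0.0039086782072313706
-0.0041622203153019229
-0.0037565742282039123
-0.0036663094570235813
-0.0029567745270088638
0.0144182041019987
-0.0069753829191304094
-0.0038816750592136026
0.0065253645217151724
0.011247724465351288
-0.0077211080302392763
-0.0050808621613828665
0.0052362059049801714
0.010177542265379695
-0.0025116458808797826
-0.014299934473886102
0.017091210321008812
0.014350695723116248
-0.0071037114584988036
-0.00065067573655583756
-0.017594687353659315
0.0056972297181910134
0.016123467982017838
-0.016372806471047163
-0.0077956851320174709
-0.0064117693375056392
-0.006811313935711558
-0.020332855956179494
0.0050096355924790668
-0.015317981399657427
-0.00024997639278263455
0.0059298472102529256
-0.0019819542148464039
0.0089200839247352611
-0.00025715070918153694
-0.0064766045058566504
0.0064635941503463981
-0.0043383274002958836
0.017726111849785026
-0.0001825971116301011
0.0085281499360053102
0.0020516290324402633
-0.030080485989204809
-0.013661119313289836
-0.0042410226014481167
0.0023680366374555788
-0.023427231203589596
0.0096169663338071185
-0.0060442573385444025
-0.0075287727936291342
-0.015556115925442458
-2.414538937380009
-1.999436681639456
-1.5949063059332627
-1.2209788295978459
-0.81004361979449069
-0.39464228277747276
-0.0045303708464991804
0.42165368501817835
0.81245746672747843
1.2059549803406988
1.6000488444953767
2.0027936078205526
-0.0070590612526762629
0.0062801715295725093
0.014802139600857037
0.010834299100832834
-0.0081324425666409097
-0.01618876849223588
-0.001096556994882412
0.0044088937091697755
0.013509939798085973
-0.013186094845335634
0.0036438459260744781
0.0023349983508851812
0.011939552612590516
-0.00027909972129577359
-0.0035729885450425298
-0.011468141361183667
-0.0051742048359362308
-0.0036212377257827241
0.023505543257891053
0.02446531375699958
-0.0016670327948427627
-0.010436674390618876
-0.01972934934074673
0.0051467163343802899
-0.010905735837348574
0.022846593255443633
-0.0088561757265795925
0.0011110642974572179
0.038102766807106656
-0.011089099979432533
0.0030756662442145378
-0.011068944722251629
0.0034765364882195999
-0.0087326453506204396
0.00077303122736923594
-0.0029686864215662141
-0.011832422404326692
0.00011292688423899649
0.0099160103605936654
0.015939674539037368
-0.013727112709291698
-0.0024961093304231947
0.011594245268555526
-0.011142223478435966
-0.025285006888503884
-0.0093590255851331225
-0.0096723945793556528
0.00047488592327795873
-0.0040373679349803423
0.0023149612824463254
-0.0042237240792674553
0.0037411839469529791
-0.0036600577499701502
0.011901014465210628
-0.0073732752525722889
0.0029066664543926581
-0.0088484956828445548
0.0020800647887083243
-0.00047730172478526253
-0.016845206461385924
-0.0014422655661895127
0.011802136655026482
0.0068139992319950441
0.0014324763088755146
-0.011923164437129161
0.01169228652789088
0.00079201708945372329
-0.0045177375276867719
0.016420282128007717
-1.5076959232159952
-1.1969663903924173
-0.88718262578816698
-0.59397777204829361
-0.30307022264537264
-0.0041841810342264137
0.30355135530046512
0.60513481114599343
0.90018607400328954
1.2131844897225625
1.4993416800016184
-0.0070029607831770379
0.005373261315213409
-0.022017823223539179
0.0039197374379841068
0.0049696095242371856
-0.0022487471542990216
-0.011171431653318846
-0.0039499460331387706
0.015498303422363064
-0.0074351447979866597
-0.023317121177295726
0.0081224544220921437
-0.0050131065720135093
-0.0051088656595235683
-0.01215364041155011
-0.00022558628347222023
0.0070123930042970684
-0.0058748202558979888
-0.0060672794141879011
0.010966402150002932
-0.0024750967708029622
-0.0015990171332324705
-0.0062577825073507481
0.0090043463560023785
-0.0099419362926622522
0.0084925038588036204
0.0080570228897643686
-0.0046760093599121982
0.0084842031372334339
0.0098676986359601745
0.0057562028851936044
0.020248420454181688
-0.0196235319122504
-0.011649209306375875
-0.013765192137308346
0.0016767993446976731
0.015846290791597162
0.016778889529762479
0.0048829669839495536
0.008786732625603243
-0.0014487487402988126
0.0046897176007420814
0.0037623547712948386
-0.0076104027505648052
-0.0029329493375086406
-0.0013484126440751764
0.013938458161730196
-0.010369886896982925
-0.021143351478036584
0.007682782182043984
-0.0081616062075348557
-0.0043610692316057428
0.0090470503128280907
-0.0076308626454831673
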