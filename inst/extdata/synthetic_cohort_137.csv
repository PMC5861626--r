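id,group,diameter_mm,entry_angle_deg
anterior_1,anterior,2.27487523503477,98.7819800619226
anterior_2,anterior,3.35237842972048,75.7640087688976
anterior_3,anterior,1.55954202794562,105.457484333006
anterior_4,anterior,3.33240803207737,66.9075476741313
anterior_5,anterior,2.19082005005646,74.8149691590658
anterior_6,anterior,2.42011996624983,67.8793467116569
anterior_7,anterior,3.1021770810757,102.936296028157
anterior_8,anterior,2.10136465349558,98.2782446378644
anterior_9,anterior,3.08725583555114,132.016281402639
anterior_10,anterior,1.34260564799964,87.7697023701266
anterior_11,anterior,1.7433793848332,71.5805415444432
anterior_12,anterior,3.41194930512405,46.3797688448514
anterior_13,anterior,1.40585600225674,64.5858370841602
anterior_14,anterior,2.20196953940325,40.7211657823403
anterior_15,anterior,2.85824508304804,160.599319971091
anterior_16,anterior,2.4833247401486,48.2553408887222
anterior_17,anterior,1.29941499627692,118.107274876718
anterior_18,anterior,1.64254672748162,87.9998999841681
anterior_19,anterior,2.00767449680491,158.276869329423
anterior_20,anterior,2.19568905336886,67.2068512166733
anterior_21,anterior,0.694353038398543,119.716646834098
anterior_22,anterior,1.50292120617204,51.2502424763821
anterior_23,anterior,2.35910624780415,66.748826504812
anterior_24,anterior,1.13438934674505,64.7366617328535
anterior_25,anterior,0.763300924032814,53.884803577805
anterior_26,anterior,1.92556841005404,160.787612851968
anterior_27,anterior,2.71903858491819,103.385572871585
anterior_28,anterior,1.97123559873109,143.096781286034
anterior_29,anterior,1.04806700529816,79.8198835106264
anterior_30,anterior,2.25457320370258,40.8978577480225
anterior_31,anterior,2.7609938399137,59.120841695304
anterior_32,anterior,2.07438914264164,114.087816887292
anterior_33,anterior,2.88618516371288,66.5663311584753
anterior_34,anterior,2.12547828490407,135.31842636779
anterior_35,anterior,3.19829576433199,143.762248039196
anterior_36,anterior,2.08327360736385,140.909500648609
anterior_37,anterior,0.670577943682841,62.5860033366732
anterior_38,anterior,3.66006766787294,51.8932398947091
anterior_39,anterior,1.7473308943279,82.6902498525369
anterior_40,anterior,0.975173139567443,82.256065453898
anterior_41,anterior,2.51991943529704,92.4013870586258
anterior_42,anterior,2.20794324834919,57.0095759107943
anterior_43,anterior,0.927655484847201,132.908721231547
anterior_44,anterior,1.40188963071869,90.7114786399843
anterior_45,anterior,1.3445793908684,92.1908475602064
anterior_46,anterior,2.93527027864275,40.0316351098308
anterior_47,anterior,2.64076694924819,127.960861402793
anterior_48,anterior,1.56182592447826,113.913144104784
anterior_49,anterior,1.17429093740118,90.643031742202
anterior_50,anterior,2.72817436682365,110.797204340314
anterior_51,anterior,1.79567175414484,121.158540710916
anterior_52,anterior,3.57885127158539,85.3287371724246
anterior_53,anterior,3.2975458375313,56.1733497518351
anterior_54,anterior,2.67300102313395,61.6230188418958
anterior_55,anterior,1.93481970647538,99.8960698484427
anterior_56,anterior,1.74808629981842,115.633300541509
anterior_57,anterior,1.46852869129529,115.138649985016
anterior_58,anterior,1.30460530762891,95.36903148889
anterior_59,anterior,2.21202318050424,102.930318850351
anterior_60,anterior,3.76838100235949,40.9419458385334
anterior_61,anterior,1.77159966640976,121.405245057935
anterior_62,anterior,0.67844029333838,144.332806501555
posterior_1,posterior,3.04745062451133,10.7970773561478
posterior_2,posterior,2.10234405979991,50.1714018344378
posterior_3,posterior,5.14190464236343,15.3735682516653
posterior_4,posterior,3.86310879492661,67.4688112946046
posterior_5,posterior,1.77510728222514,29.1862959073183
posterior_6,posterior,1.97858835280745,80.76006665861
posterior_7,posterior,2.6053130317803,39.9606856410978
posterior_8,posterior,3.63791877362733,12.0620399275244
posterior_9,posterior,4.68887484465847,55.0979082473277
posterior_10,posterior,5.03602406707431,29.4188023470974
posterior_11,posterior,3.27765481072155,59.6910599872567
posterior_12,posterior,3.69245603371668,25.571705824239
posterior_13,posterior,1.85618155602828,55.5230446099458
posterior_14,posterior,2.93480150779392,27.4058736963871
posterior_15,posterior,3.7533424582959,20.9636228279705
posterior_16,posterior,2.73616687634729,61.0334362057579
posterior_17,posterior,1.57241086104219,34.3778172240686
posterior_18,posterior,3.19659912338406,31.555430306481
posterior_19,posterior,3.51230248237432,19.7351902218875
posterior_20,posterior,4.5757433309831,83.8191156419698
posterior_21,posterior,4.764390380052,20.8975668294547
posterior_22,posterior,2.66840650003126,62.2243727371078
posterior_23,posterior,2.89847095518973,37.0619121726527
posterior_24,posterior,2.528848884285,53.2727307108098
posterior_25,posterior,2.80255923520127,85.4192288485774
posterior_26,posterior,2.18302472295127,75.4314668350157
posterior_27,posterior,1.32383079532031,27.3617665232259
posterior_28,posterior,2.88676188492982,19.0304223756962
posterior_29,posterior,3.20532820844925,19.4785092497896
posterior_30,posterior,2.20724639013008,28.3882035298916
posterior_31,posterior,3.25426293121868,65.4167251184863
posterior_32,posterior,2.25931533908635,65.6514405245462
posterior_33,posterior,3.51735755032592,17.7436923721016
posterior_34,posterior,2.92430367517197,88.8145026453749
posterior_35,posterior,3.6155560077496,36.607131991128
posterior_36,posterior,4.21175522733182,87.2694846140053
posterior_37,posterior,4.34614652439862,74.5114771796798
posterior_38,posterior,3.73248275856104,70.0866987034087
posterior_39,posterior,3.73045494796342,37.7806656957041
posterior_40,posterior,1.68516695789015,10.8823158423734
posterior_41,posterior,4.10309172634706,60.1517015453696
posterior_42,posterior,3.53684801922918,28.0840595768427
posterior_43,posterior,2.49959106293589,39.2855257306851
posterior_44,posterior,2.793310262385,59.2175079870767
posterior_45,posterior,1.42650698461842,86.9319617467995
posterior_46,posterior,5.04151037339138,17.5103877156039
posterior_47,posterior,3.56574560749355,40.5473821607138
posterior_48,posterior,2.98435472308714,69.656841800831
posterior_49,posterior,3.62031100576416,44.1134478990698
posterior_50,posterior,1.91642585813825,75.8100048741708
posterior_51,posterior,5.12880852600443,15.2951261856902
posterior_52,posterior,2.76516709125118,35.1166820944782
posterior_53,posterior,4.35557698267937,67.963572344006
posterior_54,posterior,0.905230986644255,15.8800588599306
posterior_55,posterior,3.32998916607161,19.3135383573413
posterior_56,posterior,3.04850763263202,35.5885096399834
posterior_57,posterior,2.06837375797779,81.9392303740847
posterior_58,posterior,4.23739197855144,39.6097496683019
posterior_59,posterior,1.84468870635269,24.4199535109437
posterior_60,posterior,4.21449677796293,23.080624602228
posterior_61,posterior,3.79240842013216,74.2115335745916
posterior_62,posterior,2.05419751452269,73.2195378013198
posterior_63,posterior,1.75816507598892,31.924514192101
posterior_64,posterior,3.94493934475296,79.6358700586902
posterior_65,posterior,3.1473679946205,12.5550459206343
posterior_66,posterior,2.83311623788119,12.0273063453683
posterior_67,posterior,1.77742346228291,36.6249581658931
posterior_68,posterior,3.52785337427886,31.4027128403791
posterior_69,posterior,0.999786690756419,34.2639558979527
posterior_70,posterior,4.71958364241941,27.3599370677971
posterior_71,posterior,2.49830857125754,16.9115097488375
posterior_72,posterior,1.36824832599078,84.8016290220244
posterior_73,posterior,1.24445235499065,56.3403635463151
posterior_74,posterior,2.69379840089762,42.8046776681663
posterior_75,posterior,2.20440831082565,59.4946464132918
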