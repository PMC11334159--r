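id,acronym,x_mm,y_mm,z_mm,volume_mm3
synth-01,S01,7.83608010143751,8.99462568451876,6.44344561706266,0.657253596617905
synth-02,S02,9.17507601660293,6.86129299733391,9.02445189384265,0.41156940531084
synth-03,S03,6.00718011513212,8.50441411354124,8.33263981069534,0.742474208897777
synth-04,S04,8.49405133059363,7.87796937203209,6.19671157566123,1.10705190050161
synth-05,S05,5.86145601372252,7.56897281434576,8.89311736495549,0.538207887516362
synth-06,S06,8.65779935675458,7.25837420031974,8.64099384880715,0.35113862115182
synth-07,S07,6.93318423610483,6.97199208483097,6.34868580381662,0.549579838962981
synth-08,S08,8.59630311008532,8.22535202758115,6.63813320559707,0.375205206335954
synth-09,S09,8.38182578854433,8.65273646021306,6.38543837231999,0.303533626464282
synth-10,S10,7.23845642533786,5.8842910080697,7.48449245328543,0.701475264678712
synth-11,S11,6.07542926396736,6.54117537278894,8.30913590858261,0.291461357442576
synth-12,S12,8.99726843141874,6.09562264923557,8.33346841596129,0.0982407705832461
synth-13,S13,7.43300641961458,6.24805117709558,8.33986546482661,0.285628934457369
synth-14,S14,6.87274837748502,6.61097258429672,6.32160221291092,0.737593040621659
synth-15,S15,8.40777228410169,9.24627359760008,6.44015229502503,0.938604537300649
synth-16,S16,8.85662492171937,7.2516326353219,8.02611205650541,0.342580772253061
synth-17,S17,7.69337754439348,8.11595844429301,8.65585374571053,0.383656237368036
synth-18,S18,9.10583805590721,5.94608358419563,6.63953125228991,0.558693599904552
synth-19,S19,8.19077020324535,8.31484586288418,9.05695908713952,0.139953374039251
synth-20,S20,6.96911258383899,6.94463839460468,7.83806577897513,2.7924647676221
synth-21,S21,9.11242403981924,8.83914386245905,6.13603917165181,0.328917850708088
synth-22,S22,6.01026157542275,9.35921896032039,7.91892593940072,0.719454208438182
synth-23,S23,6.29744553773616,6.11830740842187,7.57585055721936,3.91938371900725
synth-24,S24,8.69672500182759,7.89577931308322,8.75395238422881,0.684497358701147
synth-25,S25,8.04247675181299,9.23649900436558,6.03626062905425,0.364594268561758
synth-26,S26,8.12077375080942,8.39494972338133,7.70011529336846,0.141229038071941
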