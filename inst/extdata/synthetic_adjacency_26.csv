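,S01,S02,S03,S04,S05,S06,S07,S08,S09,S10,S11,S12,S13,S14,S15,S16,S17,S18,S19,S20,S21,S22,S23,S24,S25,S26
S01,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00136346269253055,0,0,0,0,0,0,0,0
S02,0,0,0,0,0,0,0,0,0,0,0,0.0138309411487236,0,0,0,0,0,0,0,0,0,0,0.000559932248592316,0,0,0
S03,0,0.000295444225525271,0,0,0,0.00100546781084256,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
S04,0,0,0,0,0,6.92939686887603e-05,0.000378588438739407,0.00357505748379596,0.00128541649181512,0.00192676420653222,0,0,0,0,0,0.00383699582304671,0,0,0,0,0,0.00111445444919784,0,0,0,0.00237513293208891
S05,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00312344623460078,0,0,0.000774895497115443,0,0,0,0,0,0.0134203920293554,0
S06,0.000518057211696933,0.00613064171538822,0.00027808871642417,0,0,0,0,0,0.00169121815168099,0,0,0,0,0,0,0,0.00532260471815619,0,0,0,0,0,0,0,0,0.0018753903724366
S07,0,0,0,0.0114924098371196,0,0,0,0.000786226707221338,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00158100111164214,0
S08,0,0.00155562035903251,0,0,0,0,0.00259767272196057,0,0,0,0,0,0,0.000672943152637343,0,0,0,0.00734818139294949,0,0,0,0.00151440495368858,0,0,0,0
S09,0.00745008574490409,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.0125435774582512,0
S10,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00830586505112691,0,0,0.000162535104700764,0.00153994792462115,0,0,0,0,0,0
S11,0.00083605365064635,0,0,0,0.00398947557407528,0,0.00158956143759331,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00283287871305555
S12,0,0,0,0,0.000924309065960207,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.000680512404954369,0,0,0,0,0,0
S13,0,0,0,0,0,0,0,0,0,0,0.00524835594396203,0.000595559680364597,0,0,0,0,0,0,0,0,0,0,0,0,0,0
S14,0,0,0,0,0,0,0.00191922037993588,0,0,0,0,0,0,0,0,0,0,0,0,0,0.000788948145149291,0,0.00362433101780547,0,0,0
S15,0.0303284635806283,0,0,0,0,0,0,0.00387422050246384,0.00327211247599309,0.000422386669090534,0,0,0,0.00169390844415041,0,0,0,0,0,0,0,0,0,0,0,0
S16,0,0,0,0,0,0.00113748897760241,0,0,0,0.00278088497129337,0,0,0,0.000555219922962908,0,0,0,0,0,0,0,0,0,0,0,0
S17,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00383774997565482,0,0,0,0,0,0,0,0,0,0.010405322898618
S18,0.000824097481828289,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
S19,0,0.000433510931443648,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.000674305747084292,0,0,0,0
S20,0.00059229473647486,0.0025778744599808,0,0,0,0.00514958296238012,0,0,0,0,0.000972650593955984,0.000643298806072669,0,0.00093176307417943,0,0,0,0,0,0,0,0,0,0,0,0
S21,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
S22,0,0,0,0,0.00425817989776577,7.78304434408555e-05,0,0,0,0,0,0,0,0,0,0,0,0.000250415480642409,0,0,0,0,0,0.00133677938499019,0,0
S23,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00080996979647,0,0
S24,0.0001042414927248,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.00279736697116692,0.000225720076690368,0,0,0
S25,0,0,0,0,6.75481663495637e-05,0,0.000859289937293922,0.000587687587012635,0,0,0,0,0,0,0.00150528924056123,0,0,0,0,0,0,0,0,0,0,0.000519979888634219
S26,0,0,0,0.00441151966410049,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
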