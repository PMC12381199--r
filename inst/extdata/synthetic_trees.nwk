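((((t16:0.2960564553,t13:0.2960564553):0.04197612514,(t15:0.2866414876,t6:0.2866414876):0.05139109277):0.03388243675,((t2:0.09679174358,t20:0.09679174358):0.2428109026,t12:0.3396026462):0.03231237094):0.6280849828,(t1:0.9937220141,((((t9:0.06180461158,(t8:0.02578117017,t5:0.02578117017):0.03602344141):0.2139700367,t14:0.2757746483):0.04509209873,t11:0.320866747):0.3873630601,(((t7:0.1083182416,t18:0.1083182416):0.4017319537,((t10:0.004321144218,t4:0.004321144218):0.05592730099,t3:0.06024844521):0.4498017501):0.03367467229,(t19:0.01517277763,t17:0.01517277763):0.5285520899):0.1645049396):0.285492207):0.006277985906);
(((t16:0.3174524672,t13:0.2585102778):0.03902513318,(t15:0.3037477008,t6:0.2840560692):0.04929634525):0.02675459216,(((t12:0.3220827525,t1:1.081826571):0.02915199047,(t2:0.1268652704,t20:0.08372442615):0.1824292531):0.6245606335,((t11:0.3501792976,((((t7:0.09769586882,t18:0.0964085879):0.3966375246,t3:0.05063446574):0.5843159162,(t10:0.004245220627,t4:0.005555742143):0.05989158299):0.02731916943,(t19:0.0178649255,t17:0.01903582767):0.5253422538):0.1574247155):0.4828731848,(((t5:0.02441380869,t14:0.2753574126):0.03517422403,t8:0.02878290538):0.2205736077,t9:0.05546937172):0.03519774481):0.3891095962):0.007411922389);
((((t16:0.3069132381,t13:0.2457690535):0.04089154952,((t2:0.09493629351,t20:0.09718427605):0.2840423639,t12:0.3365446585):0.02778803105):0.03598067116,(t15:0.2655696597,t6:0.2872100248):0.03757584978):0.6563827896,((t1:1.117219256,(((((t10:0.003654221191,t3:0.06761917777):0.05063129604,t4:0.003204604939):0.4444440311,t19:0.01933827507):0.6243769094,t17:0.01651797287):0.0343568109,(t7:0.1107551604,t18:0.1211152572):0.3325399077):0.2122590082):0.2384893754,((((t8:0.02820350667,t5:0.0268286776):0.04139041773,t14:0.2644062129):0.1829465732,t11:0.3303187395):0.04639377011,t9:0.06761379272):0.3187171725):0.006812290799);
((((t13:0.2996048173,(t15:0.2635042643,t6:0.2032797592):0.05324788176):0.033681654,t16:0.3045978563):0.03444371424,((t2:0.1125502899,t20:0.1181936823):0.2408387352,t12:0.4184768483):0.03447267575):0.694214234,(((((t1:1.140271976,t11:0.2635720861):0.3500073616,t9:0.0608028704):0.04322426259,((t8:0.03040428061,t14:0.3751021327):0.03919510134,t5:0.03046237997):0.2040051998):0.2425284826,(t19:0.01931964324,t17:0.01438903605):0.584929174):0.147210156,((t7:0.09634034362,((t10:0.005140170985,t4:0.00359629711):0.08392652298,t3:0.0670827141):0.4895976178):0.3374753249,t18:0.08123122524):0.02805189085):0.007648638041);
(((((t13:0.371053547,(t15:0.3426238736,t6:0.3141643185):0.05364773634):0.04619258592,t16:0.3231724649):0.02915852946,(t20:0.1020538021,t12:0.3258038568):0.2457230938):0.03298393671,(t1:0.9294510956,((((t9:0.06288837993,(t8:0.02640107801,t5:0.02460634045):0.03208383219):0.2302426378,t14:0.2664678422):0.04660387278,t11:0.3526349989):0.3484567462,((((t7:0.1029201946,t18:0.1200185353):0.500834276,((t10:0.004641121171,t4:0.004976288674):0.04929402127,t3:0.06567059386):0.4407500194):0.03313091982,t17:0.0140125968):0.4266068912,t19:0.01630417237):0.1510850197):0.3812988007):0.008211469317):0.5979943613,t2:0.07976119964);
((((t6:0.431587222,((t1:1.201487639,(((t9:0.05229612901,(t8:0.02713190866,t5:0.01656322743):0.02807939407):0.1583342733,t14:0.2185143725):0.04011421535,t11:0.3380688784):0.4827073447):0.358121181,(((t7:0.1098010908,t18:0.1171035694):0.4943144528,((t10:0.003550529373,t4:0.00465271178):0.05019859256,t3:0.06729998556):0.4095014601):0.03496196735,(t19:0.01573257829,t17:0.01247644674):0.4798788508):0.1910493527):0.007225001415):0.05426886219,t15:0.2229480138):0.656635455,(t2:0.1084434979,t20:0.1173177267):0.2119075653):0.03225084425,((t16:0.293783301,t13:0.2465160014):0.04256720586,t12:0.3132529675):0.02658051734);
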