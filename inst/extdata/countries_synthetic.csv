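country_id,population,cabg_rate_per_100k,mean_los_days,icu_day_cost,gw_day_cost,swi_incidence,surveillance_days,sswi_share,sswi_extra_los_days,dswi_extra_los_days
SYN01,,,17.09138704580255,880.2109375828877,,0.08454713794589043,90,0.5080313827148639,1.8476006493438035,35.852551699150354
SYN02,45798842.20047388,,16.793835534714162,,,0.05246491930820048,30,0.49820882044616155,1.7873440543189645,20.26632657740265
SYN03,40040871.255728416,,13.822847130941227,,,0.0665232958663255,30,0.5114836614606901,0.4504307603929192,20.49812245881185
SYN04,24746637.13304326,45.528366044163704,18.485975903458893,,,,,,0.7799359096679837,34.64576250454411
SYN05,65526467.32481662,26.103105191141367,11.532144938828424,1476.3075056253,1112.7890737727284,0.024065978817641734,,,,19.967601724900305
SYN06,65753509.97715723,40.86714543402195,15.297207846771926,,,0.031372894117608664,90,0.5183237231092062,3.9153462543617934,17.88261632574722
SYN07,3630601.8962292,,,1530.7925037341192,256.59328680485487,0.06223471788503229,90,,,23.899650976993144
SYN08,37136504.283570684,,,2831.872505019419,392.6414608024061,0.046408810906112194,,0.3520897925954778,,39.5967497266829
SYN09,40292492.89142899,45.19030448049307,9.5058266709093,861.6894723381847,778.3386062830687,0.08878871320188045,30,,2.5348157295957208,30.767194231040776
SYN10,23493665.501405485,36.941042114049196,19.72312532342039,2641.497415723279,,0.07216934495419264,30,0.34018766721594146,,
SYN11,57415876.46913249,,14.011226425878704,1774.2663896642625,691.2898559123278,0.06833071808703244,180,0.43382171559962446,4.578631757758558,21.112628475297242
SYN12,471158.8627891615,72.0003023557365,18.998404522193596,,789.5153866149485,,180,0.6940663644494489,4.19191136257723,32.415353645570576
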