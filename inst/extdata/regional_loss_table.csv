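region,region_area_ha,forest_ha,coniferous_ha,broadleaved_ha,woody_2020_2021,burnt_2020_2021,woody_2021_2022,burnt_2021_2022
Lviv,2182326,807144,249946,557198,1964,51,4370,127
Kyiv,2894914,812360,450456,361904,2666,2415,5659,5991
Zhytomyr,2983789,1212749,578562,634187,5806,1186,10622,1456
Kharkiv,3143488,431179,NA,NA,1518,655,2543,4632
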