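otu_name,accession,closest_match,identity_num,identity_den
Sebacinales sp1,HQ850084,Uncultured Sebacinales clone [EU625939.1],656,714
Sebacinales sp2,HQ850091,Uncultured Sebacinales clone [FN663852.1],403,433
Sebacinales sp3,HQ850092,Uncultured Sebacinales clone [EU625939.1],663,708
Sebacinales sp4,HQ850096,Salal root associated fungus [AF284137.2],414,434
Sebacinales sp5,HQ850098,Uncultured Sebacinales clone [EF127237.2],674,693
Sebacinales sp6,HQ850107,Uncultured Sebacinales clone [FJ552823.1],645,685
Sebacinales sp7,HQ850112,Uncultured Sebacinales clone [EF127237.2],430,438
Sebacinales sp8,HQ850116,Uncultured Sebacinales clone [EF127237.2],668,692
Sebacinales sp9,HQ850117,Uncultured Sebacinales clone [EF127237.2],681,691
Sebacinales sp10,HQ850124,Uncultured Sebacinales clone [HQ211970.1],673,705
Sebacinales sp11,HQ850143,Uncultured Sebacinales clone [EF127237.2],660,692
Sebacinales sp12,HQ850145,Uncultured Sebacinales clone [EF127237.2],680,689
Helotiales sp1,HQ850097,Uncultured Helotiaceae clone [FJ553302.1],541,579
Helotiales sp2,HQ850105,uncultured Helotiales [FN565272.1],533,600
Helotiales sp3,HQ850113,uncultured Helotiales [FN565272.1],569,594
Helotiales sp4,HQ850123,Uncultured Helotiaceae clone [FJ553302.1],540,579
Helotiales sp5,HQ850135,Holwaya mucida [DQ257357.1],538,592
Helotiales sp6,HQ850136,Uncultured Varicosporium clone [HQ211582.1],585,591
Helotiales sp7,HQ850137,Uncultured Helotiales clone [GU998282.1],572,612
Helotiales sp8,HQ850139,Uncultured Helotiales clone [GU998282.1],532,573
Helotiales sp9,HQ850141,Uncultured Helotiales clone [HQ260175.1],556,597
Oidiodendron maius,HQ850129,Oidiodendron maius isolate [HQ608115.1],563,582
Rhizoscyphus ericae aggregate sp1,HQ850095,Rhizoscyphus ericae aggregate [AM084704.1],511,579
Articulospora tetracladia,HQ850138,Articulospora tetracladia [EU998923.1],588,590
Mycorrhizal ascomycete of Rhododendron,HQ850090,Mycorrhizal ascomycete of Rhododendron type 3 [AB089662.1],329,347
Thelephoraceae sp1,HQ850125,Uncultured Thelephoraceae clone [EF619796.1],613,680
Agaricomycete sp1,HQ850144,Uncultured Agaricomycetes clone [FJ553957.1],620,708
Phialocephala fortinii,HQ850099,Phialocephala fortinii [AY394921.1],599,605
Dark septate endophyte 1,HQ850085,Dark septate endophyte [AF168783.1],661,668
Ascomycete sp1,HQ850100,Neoscytalidium dimidiatum [FM211431.1],427,521
Ascomycete sp2,HQ850101,Uncultured Ascomycota clone [HM239917.1],391,467
Ascomycete sp3,HQ850106,Uncultured Ascomycota clone [HM239716.1],410,418
Ascomycete sp4,HQ850130,Uncultured ascomycete clone [EU490040.1],373,377
Pezizomycotina sp1,HQ850140,Uncultured Pezizomycotina clone [FJ554411.1],565,576
Geoglossaceae sp1,HQ850142,Geoglossum umbratile [EU784257.1],800,891
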