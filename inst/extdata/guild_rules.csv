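guild,pattern
ERM,Sebacinales
ERM,Helotial
ERM,Helotiaceae
ERM,Oidiodendron
ERM,Rhizoscyphus ericae
ERM,Articulospora
ERM,Varicosporium
ERM,Holwaya
ERM,Mycorrhizal ascomycete of Rhododendron
ECM,Thelephoraceae
ECM,Agaricomycet
DSE,Phialocephala
DSE,Dark septate endophyte
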