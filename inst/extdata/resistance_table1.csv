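category,resistance,is_habitat
Broadleaf,1,TRUE
Mixed woodland,1,TRUE
Coniferous,1,TRUE
Orchard,16,FALSE
Scrub,16,FALSE
Coppice,16,FALSE
Garden,16,FALSE
Improved/Arable/Amenity,40,FALSE
Grass,40,FALSE
Heath,37,FALSE
Path,27,FALSE
Railway verge,27,FALSE
Road verge,27,FALSE
Marsh,91,FALSE
Water,130,FALSE
Urban,72,FALSE
Railway,55,FALSE
Track,27,FALSE
Building,1000,FALSE
Rock,1000,FALSE
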