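lccs_code,lccs_label,igbp_code,igbp_class,model_pft
0,no_data,NA,nodata,NA
10,cropland_rainfed,12,CRO,CRO
11,cropland_rainfed_herbaceous,12,CRO,CRO
12,cropland_rainfed_tree_or_shrub,12,CRO,CRO
20,cropland_irrigated,12,CRO,CRO
30,mosaic_cropland_gt50,14,CVM,CRO
40,mosaic_natural_gt50,9,SAV,SAV
50,tree_broadleaved_evergreen,2,EBF,EBF
60,tree_broadleaved_deciduous,4,DBF,DBF
61,tree_broadleaved_deciduous_closed,4,DBF,DBF
62,tree_broadleaved_deciduous_open,8,WSA,WSA
70,tree_needleleaved_evergreen,1,ENF,ENF
71,tree_needleleaved_evergreen_closed,1,ENF,ENF
72,tree_needleleaved_evergreen_open,1,ENF,ENF
80,tree_needleleaved_deciduous,3,DNF,DNF
81,tree_needleleaved_deciduous_closed,3,DNF,DNF
82,tree_needleleaved_deciduous_open,3,DNF,DNF
90,tree_mixed,5,MF,MF
100,mosaic_tree_shrub_gt50,8,WSA,WSA
110,mosaic_herbaceous_gt50,10,GRA,GRA
120,shrubland,7,OSH,OSH
121,shrubland_evergreen,7,OSH,OSH
122,shrubland_deciduous,7,OSH,OSH
130,grassland,10,GRA,GRA
140,lichens_mosses,10,GRA,GRA
150,sparse_vegetation,16,BSV,NA
151,sparse_tree,16,BSV,NA
152,sparse_shrub,16,BSV,NA
153,sparse_herbaceous,16,BSV,NA
160,tree_flooded_fresh,11,WET,WET
170,tree_flooded_saline,11,WET,WET
180,shrub_herbaceous_flooded,11,WET,WET
190,urban,13,URB,NA
200,bare_areas,16,BSV,NA
201,bare_areas_consolidated,16,BSV,NA
202,bare_areas_unconsolidated,16,BSV,NA
210,water,17,WAT,NA
220,snow_ice,15,SNO,NA
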