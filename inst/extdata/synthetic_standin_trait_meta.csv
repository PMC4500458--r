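trait,kind,log_transform,unit
floating_leaf,binary12,FALSE,"1=no,2=yes"
perennial,binary12,FALSE,"1=no,2=yes"
tuber,binary12,FALSE,"1=no,2=yes"
mean_julian_flowering_date,continuous,TRUE,day
flowering_duration,continuous,TRUE,day
ramet_size,continuous,TRUE,mg
shoot_height,continuous,TRUE,cm
stem_diameter,continuous,FALSE,mm
sla,continuous,TRUE,m2 kg-1
ldmc,continuous,TRUE,g g-1
lamina_thickness,continuous,FALSE,mm
rooting_depth,continuous,FALSE,cm
sdmc,continuous,TRUE,g g-1
leaf_n,continuous,TRUE,mg g-1
leaf_c,continuous,TRUE,mg g-1
leaf_cn,continuous,TRUE,g g-1
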