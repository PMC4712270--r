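region,group,capillary_id,image_id,luminal_membrane,tight_junction,basal_membrane,astroglia
frontal_cortex,control,1,1,smooth,intact,intact,intact
frontal_cortex,control,1,2,smooth,intact,intact,intact
frontal_cortex,control,1,3,smooth,intact,intact,intact
frontal_cortex,control,1,4,smooth,discontinuous,intact,intact
frontal_cortex,control,2,1,smooth,intact,intact,edematous
frontal_cortex,control,2,2,smooth,intact,intact,intact
frontal_cortex,control,2,3,smooth,intact,increased_thickness,intact
frontal_cortex,control,2,4,smooth,intact,intact,intact
frontal_cortex,control,3,1,smooth,intact,intact,intact
frontal_cortex,control,3,2,smooth,intact,intact,intact
frontal_cortex,control,3,3,protrusions,intact,intact,intact
frontal_cortex,control,3,4,smooth,intact,intact,intact
frontal_cortex,1d,1,1,smooth,discontinuous,intact,edematous
frontal_cortex,1d,1,2,protrusions,intact,detachment,intact
frontal_cortex,1d,1,3,smooth,intact,increased_thickness,intact
frontal_cortex,1d,1,4,smooth,intact,increased_thickness,intact
frontal_cortex,1d,2,1,smooth,discontinuous,increased_thickness,edematous
frontal_cortex,1d,2,2,protrusions,intact,intact,edematous
frontal_cortex,1d,2,3,smooth,intact,detachment,edematous
frontal_cortex,1d,2,4,smooth,intact,intact,intact
frontal_cortex,1d,3,1,smooth,discontinuous,intact,intact
frontal_cortex,1d,3,2,protrusions,discontinuous,increased_thickness,intact
frontal_cortex,1d,3,3,protrusions,discontinuous,intact,intact
frontal_cortex,1d,3,4,smooth,discontinuous,intact,intact
frontal_cortex,3d,1,1,smooth,discontinuous,intact,edematous
frontal_cortex,3d,1,2,protrusions,discontinuous,increased_thickness,edematous
frontal_cortex,3d,1,3,smooth,discontinuous,intact,intact
frontal_cortex,3d,1,4,smooth,discontinuous,increased_thickness,intact
frontal_cortex,3d,2,1,protrusions,intact,increased_thickness,intact
frontal_cortex,3d,2,2,smooth,intact,intact,intact
frontal_cortex,3d,2,3,protrusions,discontinuous,detachment,edematous
frontal_cortex,3d,2,4,protrusions,discontinuous,detachment,edematous
frontal_cortex,3d,3,1,smooth,discontinuous,detachment,intact
frontal_cortex,3d,3,2,smooth,intact,intact,intact
frontal_cortex,3d,3,3,protrusions,discontinuous,intact,intact
frontal_cortex,3d,3,4,protrusions,intact,detachment,intact
frontal_cortex,21d,1,1,smooth,intact,increased_thickness,edematous
frontal_cortex,21d,1,2,smooth,intact,intact,intact
frontal_cortex,21d,1,3,protrusions,intact,increased_thickness,edematous
frontal_cortex,21d,1,4,protrusions,intact,intact,edematous
frontal_cortex,21d,2,1,smooth,discontinuous,intact,intact
frontal_cortex,21d,2,2,smooth,discontinuous,intact,intact
frontal_cortex,21d,2,3,protrusions,intact,intact,intact
frontal_cortex,21d,2,4,smooth,discontinuous,increased_thickness,edematous
frontal_cortex,21d,3,1,smooth,discontinuous,intact,edematous
frontal_cortex,21d,3,2,smooth,discontinuous,detachment,intact
frontal_cortex,21d,3,3,smooth,discontinuous,increased_thickness,intact
frontal_cortex,21d,3,4,smooth,intact,detachment,edematous
hippocampus,control,1,1,smooth,intact,intact,intact
hippocampus,control,1,2,smooth,intact,intact,edematous
hippocampus,control,1,3,smooth,intact,intact,intact
hippocampus,control,1,4,smooth,intact,intact,intact
hippocampus,control,2,1,protrusions,intact,intact,intact
hippocampus,control,2,2,smooth,intact,detachment,intact
hippocampus,control,2,3,smooth,intact,intact,intact
hippocampus,control,2,4,smooth,intact,intact,intact
hippocampus,control,3,1,smooth,intact,intact,intact
hippocampus,control,3,2,smooth,intact,intact,intact
hippocampus,control,3,3,smooth,intact,intact,intact
hippocampus,control,3,4,smooth,intact,detachment,intact
hippocampus,1d,1,1,smooth,discontinuous,intact,intact
hippocampus,1d,1,2,protrusions,discontinuous,intact,intact
hippocampus,1d,1,3,protrusions,discontinuous,increased_thickness,intact
hippocampus,1d,1,4,smooth,discontinuous,increased_thickness,edematous
hippocampus,1d,2,1,smooth,intact,intact,intact
hippocampus,1d,2,2,smooth,intact,intact,edematous
hippocampus,1d,2,3,smooth,discontinuous,intact,edematous
hippocampus,1d,2,4,protrusions,intact,detachment,edematous
hippocampus,1d,3,1,smooth,intact,increased_thickness,edematous
hippocampus,1d,3,2,protrusions,discontinuous,increased_thickness,intact
hippocampus,1d,3,3,smooth,discontinuous,intact,edematous
hippocampus,1d,3,4,smooth,discontinuous,intact,intact
hippocampus,3d,1,1,protrusions,discontinuous,detachment,intact
hippocampus,3d,1,2,protrusions,intact,intact,intact
hippocampus,3d,1,3,smooth,discontinuous,intact,intact
hippocampus,3d,1,4,protrusions,intact,increased_thickness,edematous
hippocampus,3d,2,1,protrusions,discontinuous,intact,intact
hippocampus,3d,2,2,protrusions,discontinuous,increased_thickness,edematous
hippocampus,3d,2,3,smooth,intact,increased_thickness,edematous
hippocampus,3d,2,4,protrusions,discontinuous,increased_thickness,edematous
hippocampus,3d,3,1,smooth,discontinuous,detachment,edematous
hippocampus,3d,3,2,smooth,discontinuous,detachment,intact
hippocampus,3d,3,3,protrusions,intact,detachment,edematous
hippocampus,3d,3,4,protrusions,intact,intact,intact
hippocampus,21d,1,1,smooth,intact,increased_thickness,intact
hippocampus,21d,1,2,smooth,discontinuous,intact,edematous
hippocampus,21d,1,3,smooth,discontinuous,intact,intact
hippocampus,21d,1,4,smooth,discontinuous,intact,intact
hippocampus,21d,2,1,smooth,intact,intact,edematous
hippocampus,21d,2,2,smooth,intact,detachment,edematous
hippocampus,21d,2,3,smooth,intact,increased_thickness,edematous
hippocampus,21d,2,4,smooth,discontinuous,intact,edematous
hippocampus,21d,3,1,smooth,intact,increased_thickness,edematous
hippocampus,21d,3,2,smooth,intact,intact,intact
hippocampus,21d,3,3,smooth,intact,intact,edematous
hippocampus,21d,3,4,smooth,intact,intact,edematous
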