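endpoint,species,treatment,mean,sd,n
lesion_diameter_um,mouse,Cryo,911.61,52.59,4
lesion_diameter_um,mouse,Laser,775.89,56.11,5
lesion_diameter_um,rat,Cryo,686.44,42.98,6
lesion_diameter_um,rat,Laser,519.19,30.59,6
lesion_diameter_um,rabbit,Cryo,415.32,28.43,3
lesion_diameter_um,rabbit,Laser,313.65,29.35,3
thickness_ratio,mouse,Cryo,0.41,0.01,4
thickness_ratio,mouse,Laser,0.50,0.03,5
thickness_ratio,rat,Cryo,0.46,0.03,6
thickness_ratio,rat,Laser,0.51,0.01,6
thickness_ratio,rabbit,Cryo,0.45,0.01,3
thickness_ratio,rabbit,Laser,0.51,0.01,3
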