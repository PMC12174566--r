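code,name,organ,n_points
LU,Lung Meridian of Hand-Taiyin,lung,11
LI,Large Intestine Meridian of Hand-Yangming,large_intestine,20
ST,Stomach Meridian of Foot-Yangming,stomach,45
SP,Spleen Meridian of Foot-Taiyin,spleen,21
HT,Heart Meridian of Hand-Shaoyin,heart,9
SI,Small Intestine Meridian of Hand-Taiyang,small_intestine,19
BL,Bladder Meridian of Foot-Taiyang,bladder,67
KI,Kidney Meridian of Foot-Shaoyin,kidney,27
PC,Pericardium Meridian of Hand-Jueyin,pericardium,9
TE,Triple Energizer Meridian of Hand-Shaoyang,triple_energizer,23
GB,Gallbladder Meridian of Foot-Shaoyang,gallbladder,44
LR,Liver Meridian of Foot-Jueyin,liver,14
CV,Conception Vessel Meridian,,24
GV,Governor Vessel Meridian,,28
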