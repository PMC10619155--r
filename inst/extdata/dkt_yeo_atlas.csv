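base_index,roi_label,abbrev,lobe,network,braak_stage,cortical
1,Hippocampus,HIPP,Subcortical,Subcortical,2,FALSE
2,Entorhinal,ENT,Temporal,Limbic,1,TRUE
3,Amygdala,AMYG,Subcortical,Subcortical,3,FALSE
4,Thalamus Proper,THALP,Subcortical,Subcortical,NA,FALSE
5,Caudate,CAUD,Subcortical,Subcortical,NA,FALSE
6,Putamen,PUT,Subcortical,Subcortical,NA,FALSE
7,Pallidum,PAL,Subcortical,Subcortical,NA,FALSE
8,Accumbens Area,ACUM,Subcortical,Subcortical,NA,FALSE
9,Caudal Anterior Cingulate,CAC,Cingulate,Salience/VentralAttention,4,TRUE
10,Caudal Middle Frontal,CMF,Frontal,Control,5,TRUE
11,Cuneus,CUN,Occipital,Visual,6,TRUE
12,Fusiform,FUS,Temporal,Visual,3,TRUE
13,Inferior Parietal,INFP,Parietal,DefaultMode,5,TRUE
14,Inferior Temporal,IT,Temporal,Limbic,4,TRUE
15,Isthmus Cingulate,ISTC,Cingulate,DefaultMode,4,TRUE
16,Lateral Occipital,LOCC,Occipital,Visual,5,TRUE
17,Lateral Orbitofrontal,LORB,Frontal,Limbic,5,TRUE
18,Lingual,LIN,Occipital,Visual,3,TRUE
19,Medial Orbitofrontal,MORB,Frontal,Limbic,5,TRUE
20,Middle Temporal,MT,Temporal,DefaultMode,4,TRUE
21,Parahippocampal,PARH,Temporal,DefaultMode,3,TRUE
22,Paracentral,PARC,Frontal,Somatomotor,6,TRUE
23,Pars Opercularis,POPE,Frontal,Salience/VentralAttention,5,TRUE
24,Pars Orbitalis,PORB,Frontal,DefaultMode,5,TRUE
25,Pars Triangularis,PTRI,Frontal,DefaultMode,5,TRUE
26,Pericalcarine,PCAL,Occipital,Visual,6,TRUE
27,Postcentral,PSTS,Parietal,Somatomotor,6,TRUE
28,Posterior Cingulate,PC,Cingulate,DefaultMode,4,TRUE
29,Precentral,PREC,Frontal,Somatomotor,6,TRUE
30,Precuneus,PCUN,Parietal,DefaultMode,5,TRUE
31,Rostral Anterior Cingulate,RAC,Cingulate,DefaultMode,4,TRUE
32,Rostral Middle Frontal,RMF,Frontal,Control,5,TRUE
33,Superior Frontal,SF,Frontal,DefaultMode,5,TRUE
34,Superior Parietal,SP,Parietal,DorsalAttention,5,TRUE
35,Superior Temporal,ST,Temporal,Somatomotor,5,TRUE
36,Supramarginal,SMAR,Parietal,Salience/VentralAttention,5,TRUE
37,Transverse Temporal,TT,Temporal,Somatomotor,3,TRUE
38,Insula,INS,Cingulate,Salience/VentralAttention,4,TRUE
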