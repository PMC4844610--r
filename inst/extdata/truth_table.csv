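id,label,manipulations,expected_FI,expected_POMC,expected_AgRP,expected_OXT
1,POMC knockout,lesion(POMC),increase,n/a,n/a,n/a
2,MC3R knockout,"zero_receptor(ALL,MCR)",increase,n/a,n/a,n/a
3,MC4R knockout,"zero_receptor(ALL,MCR)",increase,n/a,n/a,n/a
4,Y1R knockout,"zero_receptor(ALL,Y1R)",decrease,n/a,n/a,n/a
5,db/db or ob/ob,"set_substance(leptin,0)",increase,n/a,n/a,n/a
6,LepRB deletion in POMC neurons,"zero_receptor(POMC,LepRB)",no_change,n/a,n/a,n/a
7,LepRB deletion in AgRP neurons,"zero_receptor(AgRP,LepRB)",no_change,n/a,n/a,n/a
8,LepRB deletion in POMC and AgRP neurons,"zero_receptor(POMC,LepRB);zero_receptor(AgRP,LepRB)",no_change,n/a,n/a,n/a
9,LepRB deletion in NTS neurons,"zero_receptor(NTSCA,LepRB);zero_receptor(NTSGLP1,LepRB)",increase,n/a,n/a,n/a
10,LepRB deletion in GABAergic neurons,"zero_receptor(AgRP,LepRB);zero_receptor(NGABA,LepRB);zero_receptor(LHGal,LepRB);zero_receptor(NT,LepRB)",increase,n/a,n/a,n/a
11,LepRB expressed only in POMC neurons,"zero_receptor(AgRP,LepRB);zero_receptor(NGABA,LepRB);zero_receptor(LHGal,LepRB);zero_receptor(NT,LepRB);zero_receptor(NTSCA,LepRB);zero_receptor(NTSGLP1,LepRB);zero_receptor(VTA,LepRB)",increase,n/a,n/a,n/a
12,5HT1B receptor knockout,"zero_receptor(ALL,FHT1BR)",no_change,n/a,n/a,n/a
13,5HT2C receptor knockout,"zero_receptor(ALL,FHT2CR)",increase,n/a,n/a,n/a
14,Photo-stimulation of AgRP neurons,stim(AgRP),increase,n/a,n/a,n/a
15,Photo-stimulation of AgRP projection to PVH,"stim_proj(AgRP,OXT)",increase,n/a,n/a,n/a
16,Photo-stimulation of AgRP projection to PVH and photo-stimulation of PVH,"stim_proj(AgRP,OXT);stim(OXT)",no_change,n/a,n/a,n/a
17,Simultaneous photo-stimulation of AgRP neurons and chemo-inhibition of AgRP projection to PVH,"stim(AgRP);block_proj(AgRP,OXT)",increase,n/a,n/a,n/a
18,Photo-stimulation of AgRP projections to PVH while blocking GABA receptors on PVH,"stim_proj(AgRP,OXT);zero_receptor(OXT,GABAR)",no_change,n/a,n/a,n/a
19,Photo-stimulation of AgRP projections to PVH while blocking Y1R receptors on PVH,"stim_proj(AgRP,OXT);zero_receptor(OXT,Y1R)",no_change,n/a,n/a,n/a
20,Chemogenetic activation of AgRP neurons while blocking GABA receptors on PVH,"stim(AgRP);zero_receptor(OXT,GABAR)",increase,n/a,n/a,n/a
21,Chemogenetic activation of AgRP neurons while blocking Y1R receptors on PVH,"stim(AgRP);zero_receptor(OXT,Y1R)",increase,n/a,n/a,n/a
22,Chemo-inhibition of AgRP neurons,inhibit(AgRP),decrease,n/a,n/a,n/a
23,Simultaneous photo-stimulation of AgRP neurons and POMC neurons,"stim(AgRP);stim(POMC)",increase,n/a,n/a,n/a
24,Chemo-inhibition of PVH neurons,inhibit(OXT),increase,n/a,n/a,n/a
25,Photo-stimulation of AgRP projection to LH,"stim_proj(AgRP,OX)",increase,n/a,n/a,n/a
26,Leptin administration,"set_substance(leptin,2)",decrease,excitation,inhibition,excitation
27,Ghrelin administration,"set_substance(ghrelin,2)",increase,inhibition,excitation,n/a
28,5HT1B receptor agonist administration,"set_drug(FHT1Bag,1)",n/a,n/a,inhibition,n/a
29,5HT2C receptor agonist administration,"set_drug(FHT2Cag,1)",decrease,excitation,n/a,n/a
30,alpha-MSH administration,"set_drug(aMSHx,1)",decrease,n/a,n/a,excitation
31,Glucose administration,"set_substance(glucose,2)",no_change,n/a,n/a,n/a
32,GLP-1 administration,"set_drug(GLP1x,1)",decrease,n/a,n/a,n/a
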