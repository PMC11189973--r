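dataset,variable,tissue,mean,sd,n,min,mode,max,source
site_specific,baf_stem,stem,0.89,0.46,6,NA,NA,NA,Kolleberga field experiment (triplicate plots; first 2 years)
site_specific,baf_leaves,leaves,0.13,0.08,6,NA,NA,NA,Kolleberga field experiment (triplicate plots; first 2 years)
site_specific,bmp_stem,stem,0.0783,0.0416,6,NA,NA,NA,Kolleberga field experiment (triplicate plots; first 2 years)
site_specific,bmp_leaves,leaves,0.190,0.0808,6,NA,NA,NA,Kolleberga field experiment (triplicate plots; first 2 years)
literature,baf_stem,stem,5.74,3.35,15,NA,NA,NA,Pumpkin (Cucurbita pepo ssp. pepo cv. Howden) DDX field studies
literature,baf_leaves,leaves,0.435,0.203,15,NA,NA,NA,Pumpkin (Cucurbita pepo ssp. pepo cv. Howden) DDX field studies
literature,bmp_stem,stem,0.799,0.690,15,NA,NA,NA,Pumpkin (Cucurbita pepo ssp. pepo cv. Howden) DDX field studies
literature,bmp_leaves,leaves,0.410,0.312,15,NA,NA,NA,Pumpkin (Cucurbita pepo ssp. pepo cv. Howden) DDX field studies
metabolite:sum-DDX,baf_stem,stem,0.890,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:sum-DDX,baf_leaves,leaves,0.134,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:sum-DDX,c_soil_i,NA,10,NA,6,NA,NA,NA,Initial soil concentration for the metabolite
metabolite:pp-DDT,baf_stem,stem,0.718,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:pp-DDT,baf_leaves,leaves,0.114,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:pp-DDT,c_soil_i,NA,7.9,NA,6,NA,NA,NA,Initial soil concentration for the metabolite
metabolite:op-DDT,baf_stem,stem,2.67,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:op-DDT,baf_leaves,leaves,0.286,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:op-DDT,c_soil_i,NA,1.0,NA,6,NA,NA,NA,Initial soil concentration for the metabolite
metabolite:pp-DDD,baf_stem,stem,1.63,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:pp-DDD,baf_leaves,leaves,0.114,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:pp-DDD,c_soil_i,NA,0.48,NA,6,NA,NA,NA,Initial soil concentration for the metabolite
metabolite:pp-DDE,baf_stem,stem,1.08,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:pp-DDE,baf_leaves,leaves,0.199,NA,6,NA,NA,NA,Site mean BAF per metabolite; BMP shared with site_specific (assumption)
metabolite:pp-DDE,c_soil_i,NA,0.76,NA,6,NA,NA,NA,Initial soil concentration for the metabolite
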