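character_id,body_part,family,bilateral,cut,low_includes_cut,description
01,head,binomial,FALSE,NA,NA,"Second guard seta of the post-antennal organ: 1 = at level with other guard setae, 0 = behind them"
02,head,binomial,FALSE,4,TRUE,"Number of post-labial setae on one side (4-5); coded 4 vs 5"
03,head,poisson,FALSE,NA,NA,"Number of common setae on Ant.I, one side (18-32)"
04,head,binomial,FALSE,4,TRUE,"Total number of sensilla on Ant.I (4-5); coded <=4 vs 5"
05,head,binomial,TRUE,0,TRUE,"Additional sensillum on lateral side of Ant.III (0-2); coded absent vs present"
06,thorax,binomial,FALSE,3,TRUE,"Number of setae on upper subcoxa of leg II (3-4, rare 2 and 5); coded <=3 vs >=4"
07,thorax,poisson,FALSE,NA,NA,"Number of setae on lower subcoxa of leg II (6-11)"
08,thorax,poisson,FALSE,NA,NA,"Number of setae on upper subcoxa of leg III (4-9)"
09,thorax,poisson,FALSE,NA,NA,"Number of setae on lower subcoxa of leg III (7-14)"
10,thorax,binomial,FALSE,NA,NA,"Inner tooth on claw of leg III: 1 = present, 0 = absent or indistinct"
11,thorax,binomial,FALSE,1,TRUE,"Number of ventral setae on Th.III, one side (1-4); coded 1 vs >=2"
12,abdomen,poisson,TRUE,NA,NA,"Number of anterior setae on dens (22-38)"
13,abdomen,poisson,TRUE,NA,NA,"Number of posterior setae in basal group on dens (4-9)"
14,abdomen,binomial,TRUE,3,TRUE,"Number of posterior setae in outer-proximal group on dens (2-4); coded <=3 vs 4"
15,abdomen,binomial,TRUE,3,TRUE,"Number of posterior setae in inner-proximal group on dens (2-4); coded <=3 vs 4"
16,abdomen,binomial,FALSE,2,TRUE,"Number of apical setae on posterior side of manubrium ((0-1) 2-4 (5)); coded <=2 vs >=3"
17,abdomen,binomial,TRUE,1,TRUE,"Number of posterior setae in lateral parts of manubrium, per side ((0) 1-2 (3)); coded <=1 vs >=2"
18,abdomen,poisson,TRUE,NA,NA,"Number of anterior setae on manubrium, per side (11-27)"
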