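item,category,year,currency,amount,lifespan
vehicles,start_up,2013,INTL2013,180000,
staff recruitment and training,start_up,2013,INTL2013,120000,
intervention design and piloting,start_up,2013,INTL2013,62083,
field staff salaries,implementation,2013,INTL2013,1500000,
volunteer facilitator support,implementation,2013,INTL2013,280000,
group materials,implementation,2013,MWK,10200000,
bicycles,implementation,2013,INTL2013,45000,5
programme office rent and admin,joint,2013,INTL2013,255194,
retraining of facilitators,maintenance,2013,INTL2013,27250,
external technical experts,external,2013,INTL2013,120067,
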