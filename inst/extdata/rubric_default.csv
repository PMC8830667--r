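barrier_id,variant,level,score
schedule,generic,Low,0
schedule,generic,Medium-Low,0.25
schedule,generic,Medium,0.5
schedule,generic,Medium-High,0.75
schedule,generic,High,1
temperature,generic,Low,0
temperature,generic,Medium-Low,0.25
temperature,generic,Medium,0.5
temperature,generic,Medium-High,0.8
temperature,generic,High,1
administration,generic,Low,0
administration,generic,Medium-Low,0.4
administration,generic,Medium,0.7
administration,generic,Medium-High,0.9
administration,generic,High,1
acceptability,generic,Low,0
acceptability,generic,Medium-Low,0.3
acceptability,generic,Medium,0.4
acceptability,generic,Medium-High,0.7
acceptability,generic,High,1
acceptability,pork_product,Low,0
acceptability,pork_product,Medium-Low,0.75
acceptability,pork_product,Medium,0.9
acceptability,pork_product,Medium-High,0.95
acceptability,pork_product,High,1
doses_per_container,generic,Low,0
doses_per_container,generic,Medium-Low,0.2
doses_per_container,generic,Medium,0.4
doses_per_container,generic,Medium-High,0.75
doses_per_container,generic,High,1
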