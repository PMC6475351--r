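year,beta_hat,epsilon_hat,w_bar,n_households,n_clusters,expenditure_elasticity_published,price_elasticity_published
2005,0.234,-0.056,0.0886,233,184,0.132,-0.326
2009,0.115,-0.065,0.0767,147,130,0.043,-0.258
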