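(((((((((((((((((human:0.007,chimp:0.007):0.002,gorilla:0.009):0.009,orangutan:0.018):0.014,rhesus:0.032):0.022,marmoset:0.066):0.015,(tarsier:0.08,(mouse_lemur:0.09,bushbaby:0.1):0.01):0.005):0.01,tree_shrew:0.15):0.005,((((mouse:0.35,rat:0.33):0.06,kangaroo_rat:0.42):0.02,(guinea_pig:0.23,squirrel:0.17):0.02):0.02,(rabbit:0.21,pika:0.26):0.05):0.01):0.02,((shrew:0.28,hedgehog:0.23):0.03,((microbat:0.15,megabat:0.12):0.04,(((cow:0.18,(dolphin:0.09,alpaca:0.12):0.02):0.02,horse:0.12):0.01,(dog:0.13,cat:0.1):0.04):0.01):0.02):0.02):0.01,((elephant:0.11,rock_hyrax:0.15):0.02,tenrec:0.27):0.03):0.005,(armadillo:0.12,sloth:0.1):0.05):0.10,opossum:0.36):0.06,platypus:0.46):0.12,((chicken:0.09,zebra_finch:0.1):0.25,lizard:0.4):0.12):0.08,frog:0.7):0.1,(((tetraodon:0.2,fugu:0.18):0.15,(stickleback:0.25,medaka:0.32):0.05):0.1,zebrafish:0.45):0.3):0.2,lamprey:1.2);
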