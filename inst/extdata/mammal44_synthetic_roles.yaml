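# Synthetic stand-in species tree roles for the 44-species mammalian
# alignment set. Constructed fixture: topology and branch lengths are
# literature-plausible, not estimated from data.
loss_search:
  - mouse
  - rat
  - guinea_pig
  - cow
  - horse
  - dog
  - elephant
presence_only:
  - alpaca
  - armadillo
  - bushbaby
  - cat
  - chimp
  - dolphin
  - frog
  - fugu
  - gorilla
  - hedgehog
  - human
  - kangaroo_rat
  - lamprey
  - marmoset
  - medaka
  - megabat
  - microbat
  - mouse_lemur
  - orangutan
  - pika
  - rabbit
  - rhesus
  - rock_hyrax
  - shrew
  - sloth
  - squirrel
  - stickleback
  - tarsier
  - tenrec
  - tetraodon
  - tree_shrew
  - zebrafish
outgroup:
  - opossum
  - platypus
  - chicken
  - lizard
  - zebra_finch
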