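                        1         11        
divergence              90000200902000009020
pattern                 *       *           
A1                      DKLAGYSTRDEFWHKNPLQA
A2                      DKLAGYSTRDEFWHINPLQC
fg (0.5 wt/3)           !!6!!!!!!!!6!!6!!!!6
bg (0.5 wt/3)           0!!!!6!!0!6!!!!!0!6!
insertions              00003000000000000000
deletions               00000000000000000000
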