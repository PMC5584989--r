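journal	field
journal_01	Neuroscience & Behavior
journal_02	Neuroscience & Behavior
journal_03	Neuroscience & Behavior
journal_04	Neuroscience & Behavior
journal_04	Clinical Medicine
journal_05	Clinical Medicine
journal_06	Clinical Medicine
journal_07	Clinical Medicine
journal_08	Microbiology
journal_09	Microbiology
journal_10	Microbiology
journal_11	Immunology
journal_12	Immunology
journal_13	Immunology
journal_14	Plant & Animal Science
journal_15	Plant & Animal Science
journal_16	Plant & Animal Science
journal_17	Multidisciplinary
journal_17	Clinical Medicine
journal_18	Multidisciplinary
journal_19	Multidisciplinary
journal_20	Multidisciplinary
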