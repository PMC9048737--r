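genus	side
Escherichia	case
Veillonella	case
Streptococcus	case
Actinomyces	case
Roseburia	control
Parabacteroides	control
Desulfovibrio	control
Blautia	control
Coprococcus	control
Prevotella	control
SMB53	control
Phascolarctobacterium	control
Dialister	control
Anaerostipes	control
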