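source	label	normalized
humsavar	LP/P	pathogenic
humsavar	LB/B	benign
humsavar	US	uncertain
humsavar	Disease	pathogenic
humsavar	Polymorphism	benign
humsavar	Unclassified	uncertain
clinvar	Pathogenic	pathogenic
clinvar	Likely pathogenic	pathogenic
clinvar	Pathogenic/Likely pathogenic	pathogenic
clinvar	Benign	benign
clinvar	Likely benign	benign
clinvar	Benign/Likely benign	benign
clinvar	Uncertain significance	uncertain
clinvar	Conflicting interpretations of pathogenicity	uncertain
clinvar	not provided	other
clinvar	other	other
clinvar	drug response	other
clinvar	risk factor	other
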