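bind	Binding
binds	Binding
binding	Binding
bound	Binding
interact	Binding
interaction	Binding
associate	Binding
association	Binding
complex	Binding
dimerize	Binding
attach	Binding
regulate	Regulation
regulates	Regulation
regulation	Regulation
modulate	Regulation
modulation	Regulation
control	Regulation
mediate	Regulation
activate	Positive_regulation
activates	Positive_regulation
activation	Positive_regulation
stimulate	Positive_regulation
stimulates	Positive_regulation
stimulation	Positive_regulation
induce	Positive_regulation
induces	Positive_regulation
induction	Positive_regulation
enhance	Positive_regulation
enhances	Positive_regulation
promote	Positive_regulation
upregulate	Positive_regulation
inhibit	Negative_regulation
inhibits	Negative_regulation
inhibition	Negative_regulation
suppress	Negative_regulation
suppresses	Negative_regulation
suppression	Negative_regulation
repress	Negative_regulation
represses	Negative_regulation
reduce	Negative_regulation
reduces	Negative_regulation
reduction	Negative_regulation
block	Negative_regulation
blocks	Negative_regulation
downregulate	Negative_regulation
abolish	Negative_regulation
express	Gene_expression
expresses	Gene_expression
expression	Gene_expression
overexpress	Gene_expression
coexpress	Gene_expression
transcribe	Transcription
transcribes	Transcription
transcription	Transcription
secrete	Localization
secretes	Localization
secretion	Localization
localize	Localization
localizes	Localization
localization	Localization
translocate	Localization
translocation	Localization
transport	Localization
release	Localization
releases	Localization
antagonist	Antagonist
antagonists	Antagonist
antagonism	Antagonist
antagonize	Antagonist
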