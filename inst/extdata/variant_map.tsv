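# Misspelling variants of the Gleason keyword seen in dictated reports.
# variant<TAB>canonical
gleeson	gleason
gleasen	gleason
gleasson	gleason
gleeason	gleason
glaeson	gleason
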