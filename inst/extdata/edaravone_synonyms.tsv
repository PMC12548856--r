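raw	canonical
edaravone	edaravone
radicava	edaravone
radicut	edaravone
mci-186	edaravone
edaravonum	edaravone
riluzole	riluzole
rilutek	riluzole
baclofen	baclofen
omeprazole	omeprazole
prilosec	omeprazole
acetaminophen	acetaminophen
tylenol	acetaminophen
paracetamol	acetaminophen
gabapentin	gabapentin
neurontin	gabapentin
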