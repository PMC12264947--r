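>HST1 Histatin 1, wild type (human)
DSHEKRHHGYRRKFHEKHHSHREFPFYGDYGSNYLYDN
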