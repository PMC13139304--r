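diet
faunivore
folivore
frugivore
frugivore-insectivore
insectivore
hard-object feeder
omnivore
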