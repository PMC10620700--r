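group,female,male
CN,140,99
MCI,53,42
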