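group,beds,z,n
small,<100,18993,41157
large,>=100,21829,28095
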