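{"width_um":4500,"height_um":3000,"depth_um":75}
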