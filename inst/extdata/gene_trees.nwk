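((A1_x,B1_x),(A2_x,B2_x));
(A1_y,B1_y);
((A1_z,B1_z),A2_z);
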