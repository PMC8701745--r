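cardiac_contraction	synthetic demo set	gene0001	gene0002	gene0003	gene0004	gene0005	gene0010	gene0011	gene0012
calcium_signaling	synthetic demo set	gene0003	gene0005	gene0020	gene0021	gene0022	gene0023
housekeeping	synthetic demo set	gene0100	gene0101	gene0102	gene0103	gene0104	gene0105	gene0106	gene0107	gene0108	gene0109
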